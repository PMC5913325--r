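#include <Rcpp.h>
#include <unordered_map>
#include <queue>
#include <cstdint>
using namespace Rcpp;

// Greedy overlap-layout-consensus assembler.
//
// Repeatedly merges the pair of active sequences with the longest
// suffix-prefix overlap >= min_overlap whose mismatch fraction is
// <= max_mismatch_frac; ties broken by higher overlap identity, then by the
// lexicographically smaller (representative-id, representative-id) pair,
// then by smaller placement offset. Consensus base = weighted majority of
// supporting reads, ties resolved to the alphabetically first base.
// Candidate overlaps are discovered through a shared-k-mer index
// (k = min(min_overlap, 12)); sequences are immutable once built, so a
// lazy max-heap with alive-checks yields a deterministic merge order
// (the comparator is a total order independent of insertion order).

namespace {

int base_idx(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}
const char BASES[4] = {'A', 'C', 'G', 'T'};

struct Seq {
  std::string cons;
  std::vector<std::array<int, 4>> cnt; // per-position base votes
  std::vector<int> members;            // input read indices
  std::string rep;                     // smallest member id (tie-breaking)
  bool alive = true;
};

struct Cand {
  int o;          // overlap length
  double ident;   // 1 - mismatches / o
  int si, sj;     // suffix-seq, prefix-seq (sj placed at offset d in si)
  int d;          // offset of sj's start relative to si's start (>= 0)
  std::string ri, rj;
};

struct CandLess { // priority_queue keeps the *largest*; define strict-weak order
  bool operator()(const Cand &a, const Cand &b) const {
    if (a.o != b.o) return a.o < b.o;
    if (a.ident != b.ident) return a.ident < b.ident;
    if (a.ri != b.ri) return a.ri > b.ri;
    if (a.rj != b.rj) return a.rj > b.rj;
    return a.d > b.d;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_assemble_greedy(CharacterVector reads, CharacterVector ids,
                         int min_overlap, double max_mismatch_frac) {
  const int nin = reads.size();
  std::vector<Seq> seqs;
  seqs.reserve(2 * nin + 4);

  // deduplicate byte-identical reads; multiplicity enters the vote counts
  std::unordered_map<std::string, int> first_seen;
  for (int i = 0; i < nin; ++i) {
    std::string s = as<std::string>(reads[i]);
    std::string id = as<std::string>(ids[i]);
    auto it = first_seen.find(s);
    if (it != first_seen.end()) {
      Seq &q = seqs[it->second];
      q.members.push_back(i);
      if (id < q.rep) q.rep = id;
      for (size_t p = 0; p < s.size(); ++p) {
        int b = base_idx(s[p]);
        if (b >= 0) q.cnt[p][b] += 1;
      }
      continue;
    }
    Seq q;
    q.cons = s;
    q.cnt.assign(s.size(), {0, 0, 0, 0});
    for (size_t p = 0; p < s.size(); ++p) {
      int b = base_idx(s[p]);
      if (b >= 0) q.cnt[p][b] = 1;
    }
    q.members.push_back(i);
    q.rep = id;
    first_seen[s] = (int)seqs.size();
    seqs.push_back(std::move(q));
  }

  const int k = std::max(2, std::min(min_overlap, 12));
  typedef std::vector<std::pair<int, int>> Postings; // (seq id, position)
  std::unordered_map<uint64_t, Postings> index;

  auto kmers_of = [&](const std::string &s, std::vector<std::pair<uint64_t, int>> &out) {
    out.clear();
    const int n = (int)s.size();
    if (n < k) return;
    uint64_t code = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      int b = base_idx(s[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      ++valid;
      if (valid >= k) out.push_back({code, i - k + 1});
    }
  };

  std::priority_queue<Cand, std::vector<Cand>, CandLess> heap;

  // evaluate the overlap implied by placing sj at offset d inside/after si
  auto try_candidate = [&](int si, int sj, int d) {
    if (d < 0) { std::swap(si, sj); d = -d; }
    const Seq &a = seqs[si], &b = seqs[sj];
    const int la = (int)a.cons.size(), lb = (int)b.cons.size();
    if (d >= la) return;
    int o = std::min(la - d, lb);
    if (o < min_overlap) return;
    int mm = 0, comp = 0;
    const int allowed = (int)std::floor(max_mismatch_frac * o + 1e-9);
    for (int p = 0; p < o; ++p) {
      char ca = a.cons[d + p], cb = b.cons[p];
      if (base_idx(ca) < 0 || base_idx(cb) < 0) continue;
      ++comp;
      if (ca != cb && ++mm > allowed) return;
    }
    double ident = comp ? 1.0 - (double)mm / comp : 1.0;
    heap.push(Cand{o, ident, si, sj, d, a.rep, b.rep});
  };

  std::vector<std::pair<uint64_t, int>> kms;
  std::vector<std::pair<int, int>> hits; // (other seq, diagonal)

  auto connect_and_index = [&](int sid) {
    kmers_of(seqs[sid].cons, kms);
    hits.clear();
    for (auto &km : kms) {
      auto it = index.find(km.first);
      if (it == index.end()) continue;
      Postings &pl = it->second;
      size_t w = 0;
      for (size_t r = 0; r < pl.size(); ++r) { // compact dead entries in place
        if (!seqs[pl[r].first].alive) continue;
        pl[w++] = pl[r];
        if (pl[r].first != sid)
          hits.push_back({pl[r].first, km.second - pl[r].second});
      }
      pl.resize(w);
    }
    std::sort(hits.begin(), hits.end());
    hits.erase(std::unique(hits.begin(), hits.end()), hits.end());
    for (auto &h : hits) try_candidate(sid, h.first, h.second);
    for (auto &km : kms) index[km.first].push_back({sid, km.second});
  };

  for (size_t s = 0; s < seqs.size(); ++s) connect_and_index((int)s);

  while (!heap.empty()) {
    Cand c = heap.top(); heap.pop();
    if (!seqs[c.si].alive || !seqs[c.sj].alive) continue;
    Seq &a = seqs[c.si], &b = seqs[c.sj];
    const int la = (int)a.cons.size(), lb = (int)b.cons.size();
    const int lm = std::max(la, c.d + lb);
    Seq m;
    m.cnt.assign(lm, {0, 0, 0, 0});
    for (int p = 0; p < la; ++p) m.cnt[p] = a.cnt[p];
    for (int p = 0; p < lb; ++p)
      for (int x = 0; x < 4; ++x) m.cnt[c.d + p][x] += b.cnt[p][x];
    m.cons.resize(lm);
    for (int p = 0; p < lm; ++p) {
      int best = -1, bi = -1;
      for (int x = 0; x < 4; ++x)
        if (m.cnt[p][x] > best) { best = m.cnt[p][x]; bi = x; }
      m.cons[p] = (best > 0) ? BASES[bi] : 'N';
    }
    m.members = a.members;
    m.members.insert(m.members.end(), b.members.begin(), b.members.end());
    m.rep = std::min(a.rep, b.rep);
    a.alive = false; b.alive = false;
    int mid = (int)seqs.size();
    seqs.push_back(std::move(m));
    connect_and_index(mid);
  }

  // deterministic output: longest first, then representative id
  std::vector<int> out;
  for (size_t s = 0; s < seqs.size(); ++s)
    if (seqs[s].alive) out.push_back((int)s);
  std::sort(out.begin(), out.end(), [&](int x, int y) {
    if (seqs[x].cons.size() != seqs[y].cons.size())
      return seqs[x].cons.size() > seqs[y].cons.size();
    return seqs[x].rep < seqs[y].rep;
  });

  List contigs(out.size());
  for (size_t q = 0; q < out.size(); ++q) {
    Seq &s = seqs[out[q]];
    IntegerVector support((int)s.cons.size());
    for (size_t p = 0; p < s.cons.size(); ++p) {
      int tot = 0;
      for (int x = 0; x < 4; ++x) tot += s.cnt[p][x];
      support[(int)p] = tot;
    }
    std::sort(s.members.begin(), s.members.end());
    IntegerVector mem(s.members.begin(), s.members.end());
    contigs[q] = List::create(_["sequence"] = s.cons, _["support"] = support,
                              _["members"] = mem + 1); // 1-based read indices
  }
  return contigs;
}
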
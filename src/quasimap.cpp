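// k-mer transcriptome index and greedy maximal-extension quasi-mapping.
// Hot path of the package: index construction, single-read mapping and
// batched read-pair classification. All coordinates returned to R are
// 1-based; internally everything is 0-based.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

struct Posting {
  int32_t tx;
  int32_t pos;
  uint8_t can_fwd;  // 1 if the occurrence as written equals the canonical form
};

struct IndexData {
  int k;
  int cap;
  std::vector<std::string> seqs;  // uppercased transcript sequences
  std::unordered_map<uint64_t, std::vector<Posting> > tab;
};

// reverse complement of a 2-bit packed k-mer
static inline uint64_t revcomp_code(uint64_t x, int k) {
  x = ~x;
  x = ((x & 0x3333333333333333ULL) << 2) | ((x >> 2) & 0x3333333333333333ULL);
  x = ((x & 0x0F0F0F0F0F0F0F0FULL) << 4) | ((x >> 4) & 0x0F0F0F0F0F0F0F0FULL);
  x = ((x & 0x00FF00FF00FF00FFULL) << 8) | ((x >> 8) & 0x00FF00FF00FF00FFULL);
  x = ((x & 0x0000FFFF0000FFFFULL) << 16) | ((x >> 16) & 0x0000FFFF0000FFFFULL);
  x = (x << 32) | (x >> 32);
  return x >> (64 - 2 * k);
}

static inline bool encode_at(const std::string& s, int i, int k, uint64_t& out) {
  uint64_t code = 0;
  for (int j = 0; j < k; ++j) {
    int b = base2code(s[i + j]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  out = code;
  return true;
}

static std::string rc_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': case 'a': r[i] = 'T'; break;
      case 'C': case 'c': r[i] = 'G'; break;
      case 'G': case 'g': r[i] = 'C'; break;
      case 'T': case 't': r[i] = 'A'; break;
      default: r[i] = 'N';
    }
  }
  return r;
}

// [[Rcpp::export]]
SEXP build_index_cpp(CharacterVector seqs, int k, int max_postings) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  XPtr<IndexData> xp(new IndexData(), true);
  xp->k = k;
  xp->cap = max_postings;
  int n = seqs.size();
  xp->seqs.resize(n);
  uint64_t mask = (1ULL << (2 * k)) - 1;
  for (int t = 0; t < n; ++t) {
    std::string s = as<std::string>(seqs[t]);
    for (size_t i = 0; i < s.size(); ++i) s[i] = toupper(s[i]);
    xp->seqs[t] = s;
    int L = (int)s.size();
    if (L < k) continue;
    uint64_t code = 0;
    int valid = 0;
    for (int i = 0; i < L; ++i) {
      int b = base2code(s[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        int pos = i - k + 1;
        uint64_t rc = revcomp_code(code, k);
        uint64_t can = code <= rc ? code : rc;
        Posting p;
        p.tx = t;
        p.pos = pos;
        p.can_fwd = (code <= rc) ? 1 : 0;
        xp->tab[can].push_back(p);
      }
    }
  }
  // postings cap: hyper-repetitive k-mers act as mismatches
  if (max_postings > 0) {
    for (std::unordered_map<uint64_t, std::vector<Posting> >::iterator it = xp->tab.begin();
         it != xp->tab.end(); ++it) {
      if ((int)it->second.size() > max_postings) {
        std::vector<Posting>().swap(it->second);
      }
    }
  }
  return xp;
}

// [[Rcpp::export]]
int index_n_kmers_cpp(SEXP idx) {
  XPtr<IndexData> xp(idx);
  int n = 0;
  for (std::unordered_map<uint64_t, std::vector<Posting> >::const_iterator it = xp->tab.begin();
       it != xp->tab.end(); ++it) {
    if (!it->second.empty()) ++n;
  }
  return n;
}

// All occurrences of a k-mer: forward (transcript contains the k-mer as
// written) and rc (transcript contains its reverse complement).
// [[Rcpp::export]]
List kmer_lookup_cpp(SEXP idx, std::string kmer) {
  XPtr<IndexData> xp(idx);
  int k = xp->k;
  std::vector<int> tx, pos;
  std::vector<std::string> orient;
  if ((int)kmer.size() == k) {
    uint64_t code;
    if (encode_at(kmer, 0, k, code)) {
      uint64_t rc = revcomp_code(code, k);
      uint64_t can = code <= rc ? code : rc;
      uint8_t q_can = (code <= rc) ? 1 : 0;
      std::unordered_map<uint64_t, std::vector<Posting> >::const_iterator it = xp->tab.find(can);
      if (it != xp->tab.end()) {
        for (size_t i = 0; i < it->second.size(); ++i) {
          const Posting& p = it->second[i];
          tx.push_back(p.tx + 1);
          pos.push_back(p.pos + 1);
          orient.push_back(p.can_fwd == q_can ? "fwd" : "rc");
        }
      }
    }
  }
  return List::create(_["tx"] = wrap(tx), _["pos"] = wrap(pos),
                      _["orientation"] = wrap(orient));
}

struct Seg {
  int qstart, qend;            // 0-based half-open on the query
  std::vector<int> tx, pos;    // equally ranked maximal-extension hits
};

// Greedy maximal-extension mapping of one oriented sequence: from the
// leftmost query position with an indexed k-mer, extend base-by-base along
// each hit transcript while bases agree; keep the transcripts supporting
// the maximal extension; resume after the segment end.
static void map_oriented(const std::string& s, const IndexData& I, std::vector<Seg>& segs) {
  int k = I.k;
  int n = (int)s.size();
  segs.clear();
  int i = 0;
  while (i + k <= n) {
    uint64_t code;
    if (!encode_at(s, i, k, code)) { ++i; continue; }
    uint64_t rc = revcomp_code(code, k);
    uint64_t can = code <= rc ? code : rc;
    uint8_t q_can = (code <= rc) ? 1 : 0;
    std::unordered_map<uint64_t, std::vector<Posting> >::const_iterator it = I.tab.find(can);
    if (it == I.tab.end() || it->second.empty()) { ++i; continue; }
    int best = 0;
    std::vector<int> btx, bpos;
    for (size_t h = 0; h < it->second.size(); ++h) {
      const Posting& p = it->second[h];
      if (p.can_fwd != q_can) continue;  // rc occurrences handled by the rc pass
      const std::string& t = I.seqs[p.tx];
      int tl = (int)t.size();
      int ext = k;
      while (i + ext < n && p.pos + ext < tl && s[i + ext] == t[p.pos + ext]) ++ext;
      if (ext > best) { best = ext; btx.clear(); bpos.clear(); }
      if (ext == best) { btx.push_back(p.tx); bpos.push_back(p.pos); }
    }
    if (best == 0) { ++i; continue; }
    Seg sg;
    sg.qstart = i;
    sg.qend = i + best;
    sg.tx.swap(btx);
    sg.pos.swap(bpos);
    segs.push_back(sg);
    i += best;
  }
}

struct MapResult {
  int orient;  // 0 fwd, 1 rc
  int total;   // query bases covered by segments
  std::vector<Seg> segs;
};

// Map in both orientations, keep the higher total coverage (ties -> fwd).
// A full-coverage forward hit skips the rc pass (it cannot be beaten).
static void map_best(const std::string& s0, const IndexData& I, MapResult& out) {
  std::string s(s0);
  for (size_t i = 0; i < s.size(); ++i) s[i] = toupper(s[i]);
  std::vector<Seg> f;
  map_oriented(s, I, f);
  int tf = 0;
  for (size_t i = 0; i < f.size(); ++i) tf += f[i].qend - f[i].qstart;
  if (tf == (int)s.size()) {
    out.orient = 0; out.total = tf; out.segs.swap(f);
    return;
  }
  std::string sr = rc_str(s);
  std::vector<Seg> r;
  map_oriented(sr, I, r);
  int tr = 0;
  for (size_t i = 0; i < r.size(); ++i) tr += r[i].qend - r[i].qstart;
  if (tr > tf) { out.orient = 1; out.total = tr; out.segs.swap(r); }
  else         { out.orient = 0; out.total = tf; out.segs.swap(f); }
}

static List segs_to_list(const MapResult& m) {
  int ns = (int)m.segs.size();
  IntegerVector qs(ns), qe(ns);
  List htx(ns), hpos(ns);
  for (int i = 0; i < ns; ++i) {
    qs[i] = m.segs[i].qstart + 1;
    qe[i] = m.segs[i].qend;  // 1-based inclusive end == 0-based exclusive end
    IntegerVector t(m.segs[i].tx.size()), p(m.segs[i].pos.size());
    for (size_t j = 0; j < m.segs[i].tx.size(); ++j) {
      t[j] = m.segs[i].tx[j] + 1;
      p[j] = m.segs[i].pos[j] + 1;
    }
    htx[i] = t;
    hpos[i] = p;
  }
  return List::create(_["orientation"] = m.orient == 0 ? "fwd" : "rc",
                      _["total_matched"] = m.total,
                      _["qstart"] = qs, _["qend"] = qe,
                      _["hit_tx"] = htx, _["hit_pos"] = hpos);
}

// [[Rcpp::export]]
List map_read_cpp(std::string seq, SEXP idx) {
  XPtr<IndexData> xp(idx);
  MapResult m;
  map_best(seq, *xp, m);
  return segs_to_list(m);
}

// per-transcript matched bases and leftmost mapped transcript position;
// keys and positions are 1-based
static void per_tx_coverage(const MapResult& m,
                            std::unordered_map<int, int>& bases,
                            std::unordered_map<int, int>& minpos) {
  bases.clear();
  minpos.clear();
  for (size_t i = 0; i < m.segs.size(); ++i) {
    const Seg& sg = m.segs[i];
    int len = sg.qend - sg.qstart;
    for (size_t j = 0; j < sg.tx.size(); ++j) {
      int t = sg.tx[j] + 1;
      int pp = sg.pos[j] + 1;
      bases[t] += len;
      std::unordered_map<int, int>::iterator it = minpos.find(t);
      if (it == minpos.end() || pp < it->second) minpos[t] = pp;
    }
  }
}

// Batched mapping + pair classification.
// Classes: 0 concordant, 1 mapped_read, 2 split_read, 3 other/unmapped.
// tx2gene: integer gene code per transcript (1-based, parallel to index).
// [[Rcpp::export]]
List map_classify_pairs_cpp(CharacterVector r1, CharacterVector r2, SEXP idx,
                            IntegerVector tx2gene) {
  XPtr<IndexData> xp(idx);
  const IndexData& I = *xp;
  int k = I.k;
  int n = r1.size();
  if (r2.size() != n) stop("mate vectors must have equal length");
  IntegerVector cls(n);
  List payload(n);

  std::unordered_map<int, int> b1, b2, p1, p2;
  for (int i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(r1[i]);
    std::string s2 = as<std::string>(r2[i]);
    MapResult m1, m2;
    map_best(s1, I, m1);
    map_best(s2, I, m2);
    int thr1 = (int)s1.size() - k - 1;
    int thr2 = (int)s2.size() - k - 1;

    per_tx_coverage(m1, b1, p1);
    per_tx_coverage(m2, b2, p2);
    std::vector<int> T1, T2, S;
    for (std::unordered_map<int, int>::const_iterator it = b1.begin(); it != b1.end(); ++it)
      if (it->second >= thr1) T1.push_back(it->first);
    for (std::unordered_map<int, int>::const_iterator it = b2.begin(); it != b2.end(); ++it)
      if (it->second >= thr2) T2.push_back(it->first);
    for (size_t a = 0; a < T1.size(); ++a)
      for (size_t b = 0; b < T2.size(); ++b)
        if (T1[a] == T2[b]) { S.push_back(T1[a]); break; }

    if (!S.empty()) {
      cls[i] = 0;
      IntegerVector sv(S.size());
      for (size_t a = 0; a < S.size(); ++a) sv[a] = S[a];
      payload[i] = sv;
      continue;
    }

    if (!T1.empty() && !T2.empty()) {
      // need some pair of distinct genes between the two sides
      bool distinct = false;
      for (size_t a = 0; a < T1.size() && !distinct; ++a)
        for (size_t b = 0; b < T2.size() && !distinct; ++b)
          if (tx2gene[T1[a] - 1] != tx2gene[T2[b] - 1]) distinct = true;
      if (distinct) {
        cls[i] = 1;
        IntegerVector t1(T1.size()), q1(T1.size()), t2(T2.size()), q2(T2.size());
        for (size_t a = 0; a < T1.size(); ++a) { t1[a] = T1[a]; q1[a] = p1[T1[a]]; }
        for (size_t a = 0; a < T2.size(); ++a) { t2[a] = T2[a]; q2[a] = p2[T2[a]]; }
        payload[i] = List::create(
            _["t1"] = t1, _["p1"] = q1, _["t2"] = t2, _["p2"] = q2,
            _["or1"] = m1.orient, _["or2"] = m2.orient);
        continue;
      }
    }

    // split read: one mate chimeric (first/last segments >= k, different
    // genes), the other mate anchored in one of the two genes
    bool assigned = false;
    for (int mate = 1; mate <= 2 && !assigned; ++mate) {
      const MapResult& M = (mate == 1) ? m1 : m2;
      const MapResult& O = (mate == 1) ? m2 : m1;
      int thrO = (mate == 1) ? thr2 : thr1;
      std::unordered_map<int, int>& bO = (mate == 1) ? b2 : b1;
      std::unordered_map<int, int>& pO = (mate == 1) ? p2 : p1;
      if (M.segs.size() < 2) continue;
      const Seg& A = M.segs.front();
      const Seg& B = M.segs.back();
      if (A.qend - A.qstart < k || B.qend - B.qstart < k) continue;
      // gene sets of the two sides must be disjoint
      bool overlap = false;
      for (size_t a = 0; a < A.tx.size() && !overlap; ++a)
        for (size_t b = 0; b < B.tx.size() && !overlap; ++b)
          if (tx2gene[A.tx[a]] == tx2gene[B.tx[b]]) overlap = true;
      if (overlap) continue;
      // anchor: transcripts of the other mate fully mapped (>= r-k-1) whose
      // gene belongs to either side of the split
      std::vector<int> anc, ancpos;
      for (std::unordered_map<int, int>::const_iterator it = bO.begin(); it != bO.end(); ++it) {
        if (it->second < thrO) continue;
        int g = tx2gene[it->first - 1];
        bool ok = false;
        for (size_t a = 0; a < A.tx.size() && !ok; ++a) if (tx2gene[A.tx[a]] == g) ok = true;
        for (size_t b = 0; b < B.tx.size() && !ok; ++b) if (tx2gene[B.tx[b]] == g) ok = true;
        if (ok) { anc.push_back(it->first); ancpos.push_back(pO[it->first]); }
      }
      if (anc.empty()) continue;
      cls[i] = 2;
      IntegerVector at(A.tx.size()), ap(A.pos.size()), bt(B.tx.size()), bp(B.pos.size());
      for (size_t a = 0; a < A.tx.size(); ++a) { at[a] = A.tx[a] + 1; ap[a] = A.pos[a] + 1; }
      for (size_t b = 0; b < B.tx.size(); ++b) { bt[b] = B.tx[b] + 1; bp[b] = B.pos[b] + 1; }
      payload[i] = List::create(
          _["mate"] = mate, _["orient"] = M.orient,
          _["q1s"] = A.qstart + 1, _["q1e"] = A.qend,
          _["q2s"] = B.qstart + 1, _["q2e"] = B.qend,
          _["tx1"] = at, _["pos1"] = ap,
          _["tx2"] = bt, _["pos2"] = bp,
          _["anchor_tx"] = wrap(anc), _["anchor_pos"] = wrap(ancpos),
          _["anchor_orient"] = O.orient);
      assigned = true;
    }
    if (!assigned) cls[i] = 3;
  }
  return List::create(_["class"] = cls, _["payload"] = payload);
}
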
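// Core scanning/merging kernels. All coordinates here are 0-based; the R
// wrappers convert to the package's 1-based convention.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <string>
#include <algorithm>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;  // N and IUPAC codes never match in seed/confirm space
  }
}

static inline char comp_char(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g'; case 'g': return 'c'; case 't': return 'a';
  case 'R': return 'Y'; case 'Y': return 'R'; case 'S': return 'S'; case 'W': return 'W';
  case 'K': return 'M'; case 'M': return 'K'; case 'B': return 'V'; case 'V': return 'B';
  case 'D': return 'H'; case 'H': return 'D'; case '-': return '-';
  default: return 'N';
  }
}

static std::vector<int8_t> encode(const std::string& s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t) base_code(s[i]);
  return v;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(x[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j) r[j] = comp_char(s[s.size() - 1 - j]);
    out[i] = r;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Concatenated-reference layout shared by the scanners. Candidate diagonals
// are discovered via exact anchor k-mers; the spaced-seed and confirmation
// contracts are enforced per candidate.
// ---------------------------------------------------------------------------

struct RefCat {
  int seed_w;
  std::vector<int8_t> ref;       // concatenated, negative separators
  std::vector<int> ref_id;       // per-position source (1-based), 0 = separator
  std::vector<int> ref_local;    // per-position local coordinate
};

// Best gapless confirmation window on the diagonal through (qpos, rpos_local)
// within one reference sequence. Returns identities of the best window of
// length min(conf_w, overlap) that contains the anchor column, plus that
// window length and (optionally) the best window's query start.
// Thresholding (with proportional scaling for clipped windows) is left to
// the caller.
static void confirm_on_diag2(const std::vector<int8_t>& q,
                             const std::vector<int8_t>& r,
                             int qpos, int rpos, int conf_w,
                             int* best_ident, int* win_len, int* win_start) {
  int Lq = (int) q.size(), Lr = (int) r.size();
  int d = qpos - rpos;                       // query coord - ref coord
  int qlo = std::max(0, d), qhi = std::min(Lq, Lr + d);
  int ov = qhi - qlo;
  if (ov <= 0) { *best_ident = 0; *win_len = 0; if (win_start) *win_start = qpos; return; }
  int w = std::min(conf_w, ov);
  // prefix sums of matches over the overlap
  std::vector<int> pre(ov + 1, 0);
  for (int i = 0; i < ov; ++i) {
    int qc = q[qlo + i], rc = r[qlo + i - d];
    pre[i + 1] = pre[i] + (qc >= 0 && qc == rc ? 1 : 0);
  }
  int anchor = qpos;  // anchor column must lie inside the window
  int smin = std::max(qlo, anchor - w + 1);
  int smax = std::min(qhi - w, anchor);
  if (smax < smin) { smin = qlo; smax = qhi - w; }  // anchor at clipped edge
  int best = -1, bs = smin;
  for (int s = smin; s <= smax; ++s) {
    int m = pre[s - qlo + w] - pre[s - qlo];
    if (m > best) { best = m; bs = s; }
  }
  *best_ident = best < 0 ? 0 : best;
  *win_len = w;
  if (win_start) *win_start = bs;
}

static void confirm_on_diag(const std::vector<int8_t>& q,
                            const std::vector<int8_t>& r,
                            int qpos, int rpos, int conf_w,
                            int* best_ident, int* win_len) {
  confirm_on_diag2(q, r, qpos, rpos, conf_w, best_ident, win_len, nullptr);
}

static inline bool passes_confirm(int ident, int win_len, int conf_w, int conf_min) {
  if (win_len <= 0) return false;
  double thr = (double) conf_min * (double) win_len / (double) conf_w;
  return (double) ident >= thr - 1e-9;
}

// [[Rcpp::export]]
List cpp_confirm(std::string query, std::string ref, int qanchor, int ranchor,
                 int conf_w, int conf_min) {
  std::vector<int8_t> q = encode(query), r = encode(ref);
  int ident = 0, w = 0;
  confirm_on_diag(q, r, qanchor, ranchor, conf_w, &ident, &w);
  return List::create(_["identities"] = ident, _["window"] = w,
                      _["pass"] = passes_confirm(ident, w, conf_w, conf_min));
}

// Scan one query against a set of references. Candidate diagonals are
// located by exact 12-mer anchors; each candidate must then pass a full
// spaced-seed window (seed_w, seed_min) and the confirmation window on its
// diagonal. One row is reported per confirmed (reference, diagonal), with
// qpos/rpos the best confirmation window's coordinates.
// [[Rcpp::export]]
DataFrame cpp_scan_hits(std::string query, CharacterVector refs,
                        int seed_w, int seed_min, int conf_w, int conf_min) {
  std::vector<std::string> rs(refs.size());
  std::vector<std::vector<int8_t>> renc(refs.size());
  for (R_xlen_t i = 0; i < refs.size(); ++i) {
    rs[i] = as<std::string>(refs[i]);
    renc[i] = encode(rs[i]);
  }
  const int ak = std::min(12, seed_w);
  const uint64_t amask = (1ULL << (2 * ak)) - 1;
  int allowed = seed_w - seed_min;
  // anchor index over the concatenated references
  std::vector<int8_t> cref; std::vector<int> cref_id, cref_local;
  for (size_t i = 0; i < rs.size(); ++i) {
    std::vector<int8_t> enc = encode(rs[i]);
    for (size_t j = 0; j < enc.size(); ++j) {
      cref.push_back(enc[j]); cref_id.push_back((int) i + 1); cref_local.push_back((int) j);
    }
    cref.push_back(-2); cref_id.push_back(0); cref_local.push_back(-1);
  }
  std::unordered_map<uint64_t, std::vector<int>> amap;
  {
    uint64_t key = 0; int run = 0;
    for (size_t p = 0; p < cref.size(); ++p) {
      int c = cref[p];
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t) c) & amask;
      if (++run >= ak) amap[key].push_back((int) p - ak + 1);
    }
  }
  std::vector<int8_t> q = encode(query);
  int Lq = (int) q.size();
  std::vector<int> out_q, out_ref, out_r, out_id, out_w;
  std::unordered_map<int64_t, bool> diag_done;
  uint64_t rkey = 0; int rrun = 0;
  for (int g = 0; g < Lq; ++g) {
    int qc = q[g];
    if (qc < 0) { rrun = 0; rkey = 0; continue; }
    rkey = ((rkey << 2) | (uint64_t) qc) & amask;
    if (++rrun < ak) continue;
    int ga = g - ak + 1;
    auto it = amap.find(rkey);
    if (it == amap.end()) continue;
    for (int p : it->second) {
      int rid = cref_id[p];
      if (rid == 0) continue;
      int rlocal = cref_local[p];
      int d = ga - rlocal;
      int64_t dkey = ((int64_t) rid << 32) ^ (int64_t)(d + (1 << 30));
      if (diag_done.count(dkey)) continue;
      const std::vector<int8_t>& rr = renc[rid - 1];
      int Lr = (int) rr.size();
      int qs = ga;
      if (qs + seed_w > Lq) qs = Lq - seed_w;
      if (qs - d < 0) qs = d;
      if (qs - d + seed_w > Lr) qs = Lr + d - seed_w;
      if (qs < 0 || qs + seed_w > Lq || qs - d < 0 || qs - d + seed_w > Lr)
        continue;
      int mm = 0; bool seed_ok = true;
      for (int j = 0; j < seed_w; ++j) {
        int a = q[qs + j], b = rr[qs - d + j];
        if (a < 0 || b < 0 || a != b) { if (++mm > allowed) { seed_ok = false; break; } }
      }
      if (!seed_ok) continue;  // another anchor may retry this diagonal
      diag_done[dkey] = true;
      int ident, wlen, wstart;
      confirm_on_diag2(q, rr, qs, qs - d, conf_w, &ident, &wlen, &wstart);
      if (passes_confirm(ident, wlen, conf_w, conf_min)) {
        out_q.push_back(wstart); out_ref.push_back(rid);
        out_r.push_back(wstart - d);
        out_id.push_back(ident); out_w.push_back(wlen);
      }
    }
  }
  return DataFrame::create(_["qpos"] = out_q, _["ref"] = out_ref, _["rpos"] = out_r,
                           _["identities"] = out_id, _["window"] = out_w);
}

// Best placement of each read against a set of references, both strands.
// strand +1 = read as given, -1 = reverse complement. offset = oriented read
// start expressed in reference coordinates (may be negative). A read is
// ambiguous when a second, incompatible placement scores within `margin`
// identities of the best (repeat-copy ties).
// [[Rcpp::export]]
DataFrame cpp_best_hits(CharacterVector reads, CharacterVector refs,
                        int seed_w, int seed_min, int conf_w, int conf_min,
                        int margin = 0) {
  std::vector<std::string> rs(refs.size());
  std::vector<std::vector<int8_t>> renc(refs.size());
  for (R_xlen_t i = 0; i < refs.size(); ++i) {
    rs[i] = as<std::string>(refs[i]);
    renc[i] = encode(rs[i]);
  }
  int allowed = seed_w - seed_min;
  // exact anchor k-mers accelerate candidate-diagonal discovery; the full
  // seed (17/20) + confirmation contract is still enforced per candidate
  const int ak = std::min(12, seed_w);
  const uint64_t amask = (1ULL << (2 * ak)) - 1;
  RefCat idx;
  idx.seed_w = seed_w;
  {
    size_t total = 0;
    for (const auto& r : rs) total += r.size() + 1;
    idx.ref.reserve(total); idx.ref_id.reserve(total); idx.ref_local.reserve(total);
    for (size_t i = 0; i < rs.size(); ++i) {
      std::vector<int8_t> enc = encode(rs[i]);
      for (size_t j = 0; j < enc.size(); ++j) {
        idx.ref.push_back(enc[j]);
        idx.ref_id.push_back((int) i + 1);
        idx.ref_local.push_back((int) j);
      }
      idx.ref.push_back(-2);
      idx.ref_id.push_back(0);
      idx.ref_local.push_back(-1);
    }
  }
  std::unordered_map<uint64_t, std::vector<int>> amap;
  {
    uint64_t key = 0; int run = 0;
    for (size_t p = 0; p < idx.ref.size(); ++p) {
      int c = idx.ref[p];
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t) c) & amask;
      if (++run >= ak) amap[key].push_back((int) p - ak + 1);
    }
  }

  R_xlen_t n = reads.size();
  IntegerVector best_ref(n, 0), best_strand(n, 0), best_offset(n, NA_INTEGER),
      best_id(n, 0), best_win(n, 0), n_refs_passed(n, 0);
  LogicalVector ambiguous(n, false);

  std::vector<int8_t> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    std::string rev(fwd.size(), 'N');
    for (size_t j = 0; j < fwd.size(); ++j) rev[j] = comp_char(fwd[fwd.size() - 1 - j]);
    int bi = 0, b2 = 0, bref = 0, bstrand = 0, boff = 0, bwin = 0;
    std::vector<bool> ref_pass(refs.size(), false);
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& s = strand == 0 ? fwd : rev;
      q = encode(s);
      int Lq = (int) q.size();
      std::unordered_map<int64_t, bool> diag_done;
      uint64_t rkey = 0; int rrun = 0;
      for (int g = 0; g < Lq; ++g) {
        int qc = q[g];
        if (qc < 0) { rrun = 0; rkey = 0; continue; }
        rkey = ((rkey << 2) | (uint64_t) qc) & amask;
        if (++rrun < ak) continue;
        int ga = g - ak + 1;  // anchor start in the query
        auto it = amap.find(rkey);
        if (it == amap.end()) continue;
        for (int p : it->second) {
          int rid = idx.ref_id[p];
          if (rid == 0) continue;
          int rlocal = idx.ref_local[p];
          int d = ga - rlocal;  // query coord - ref-local coord
          int64_t dkey = ((int64_t) rid << 33) ^ ((int64_t) strand << 32)
            ^ (int64_t)(d + (1 << 30));
          if (diag_done.count(dkey)) continue;
          // enforce the spaced-seed contract: a full seed window on this
          // diagonal around the anchor must pass
          int Lr = (int) renc[rid - 1].size();
          int qs = ga;
          if (qs + seed_w > Lq) qs = Lq - seed_w;
          if (qs - d < 0) qs = d;
          if (qs - d + seed_w > Lr) qs = Lr + d - seed_w;
          if (qs < 0 || qs + seed_w > Lq || qs - d < 0 || qs - d + seed_w > Lr)
            continue;  // no room for a full seed window on this diagonal
          int mm = 0; bool seed_ok = true;
          const std::vector<int8_t>& rr = renc[rid - 1];
          for (int j = 0; j < seed_w; ++j) {
            int a = q[qs + j], b = rr[qs - d + j];
            if (a < 0 || b < 0 || a != b) { if (++mm > allowed) { seed_ok = false; break; } }
          }
          if (!seed_ok) continue;  // another anchor may retry this diagonal
          diag_done[dkey] = true;
          {
            int ident, wlen;
            confirm_on_diag(q, renc[rid - 1], qs, qs - d, conf_w, &ident, &wlen);
            if (!passes_confirm(ident, wlen, conf_w, conf_min)) continue;
            ref_pass[rid - 1] = true;
            int offset = -d;  // oriented read start in ref coords
            int this_strand = strand == 0 ? 1 : -1;
            bool same_place = rid == bref && this_strand == bstrand && offset == boff;
            if (ident > bi) {
              if (bref > 0 && !same_place && bi > b2) b2 = bi;
              bi = ident; bref = rid; bstrand = this_strand;
              boff = offset; bwin = wlen;
            } else if (!same_place && ident > b2) {
              b2 = ident;
            }
          }
        }
      }
    }
    int npass = 0;
    for (size_t ri = 0; ri < ref_pass.size(); ++ri) if (ref_pass[ri]) ++npass;
    best_ref[i] = bref; best_strand[i] = bstrand;
    best_offset[i] = bref > 0 ? boff : NA_INTEGER;
    best_id[i] = bi; best_win[i] = bwin; n_refs_passed[i] = npass;
    ambiguous[i] = bref > 0 && b2 >= bi - margin && b2 > 0;
  }
  return DataFrame::create(_["read"] = seq_len(n), _["ref"] = best_ref,
                           _["strand"] = best_strand, _["offset"] = best_offset,
                           _["identities"] = best_id, _["window"] = best_win,
                           _["n_refs_passed"] = n_refs_passed, _["ambiguous"] = ambiguous);
}

// ---------------------------------------------------------------------------
// Paired-read merging
// ---------------------------------------------------------------------------

// Evaluate matches for shift t of b (already reverse-complemented) against a.
static void shift_matches(const std::vector<int8_t>& a, const std::vector<int8_t>& b,
                          int t, int* matches, int* overlap) {
  int la = (int) a.size(), lb = (int) b.size();
  int lo = std::max(0, t), hi = std::min(la, t + lb);
  int ov = hi - lo;
  if (ov <= 0) { *matches = 0; *overlap = 0; return; }
  int m = 0;
  for (int i = lo; i < hi; ++i)
    if (a[i] >= 0 && a[i] == b[i - t]) ++m;
  *matches = m; *overlap = ov;
}

// Exhaustive best gapless overlap (maximizing matches, ties to longer
// overlap then smaller shift). Used directly for percent identity and as the
// fallback path of pair merging.
// [[Rcpp::export]]
List cpp_best_overlap(std::string a, std::string b, int min_overlap) {
  std::vector<int8_t> ea = encode(a), eb = encode(b);
  int la = (int) ea.size(), lb = (int) eb.size();
  int best_m = -1, best_ov = 0, best_t = 0;
  for (int t = min_overlap - lb; t <= la - min_overlap; ++t) {
    int m, ov;
    shift_matches(ea, eb, t, &m, &ov);
    if (ov < min_overlap) continue;
    if (m > best_m || (m == best_m && ov > best_ov)) { best_m = m; best_ov = ov; best_t = t; }
  }
  if (best_m < 0) best_m = 0;
  return List::create(_["shift"] = best_t, _["matches"] = best_m, _["overlap"] = best_ov);
}

// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector r1, CharacterVector r2, List q1, List q2,
                     int min_overlap, double max_mismatch_rate) {
  const int ak = 16;  // anchor k-mer for candidate shifts
  R_xlen_t n = r1.size();
  CharacterVector mseq(n);
  List mqual(n);
  LogicalVector merged(n, false);
  IntegerVector overlap(n, 0), mismatches(n, NA_INTEGER), shift(n, NA_INTEGER);

  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(r1[i]);
    std::string s2 = as<std::string>(r2[i]);
    int l1 = (int) s1.size(), l2 = (int) s2.size();
    mseq[i] = NA_STRING; mqual[i] = R_NilValue;
    if (l1 == 0 || l2 == 0) continue;
    std::string rc2(l2, 'N');
    for (int j = 0; j < l2; ++j) rc2[j] = comp_char(s2[l2 - 1 - j]);
    std::vector<int8_t> a = encode(s1), b = encode(rc2);

    // candidate shifts from shared exact 16-mers
    std::vector<int> cand;
    if (l1 >= ak && l2 >= ak) {
      std::unordered_map<uint64_t, std::vector<int>> amap;
      uint64_t key = 0; int run = 0;
      for (int p = 0; p < l1; ++p) {
        if (a[p] < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t) a[p]) & ((1ULL << (2 * ak)) - 1);
        if (++run >= ak) amap[key].push_back(p - ak + 1);
      }
      key = 0; run = 0;
      for (int p = 0; p < l2; ++p) {
        if (b[p] < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t) b[p]) & ((1ULL << (2 * ak)) - 1);
        if (++run >= ak) {
          auto it = amap.find(key);
          if (it != amap.end())
            for (int ap : it->second) {
              int t = ap - (p - ak + 1);
              if (std::find(cand.begin(), cand.end(), t) == cand.end()) cand.push_back(t);
            }
        }
      }
    }
    int best_m = -1, best_ov = 0, best_t = 0;
    if (!cand.empty()) {
      for (int t : cand) {
        int m, ov;
        shift_matches(a, b, t, &m, &ov);
        if (ov < min_overlap) continue;
        if (m > best_m || (m == best_m && ov > best_ov)) { best_m = m; best_ov = ov; best_t = t; }
      }
    }
    if (best_m < 0) {  // fallback: exhaustive
      for (int t = min_overlap - l2; t <= l1 - min_overlap; ++t) {
        int m, ov;
        shift_matches(a, b, t, &m, &ov);
        if (ov < min_overlap) continue;
        if (m > best_m || (m == best_m && ov > best_ov)) { best_m = m; best_ov = ov; best_t = t; }
      }
    }
    if (best_m < 0) continue;
    int mm = best_ov - best_m;
    overlap[i] = best_ov; mismatches[i] = mm; shift[i] = best_t;
    if ((double) mm > max_mismatch_rate * (double) best_ov) continue;

    int t = best_t;
    int frag = t + l2;  // fragment length implied by the overlap geometry
    if (frag <= 0) continue;
    IntegerVector iq1 = q1[i], iq2 = q2[i];
    bool have_q = iq1.size() == l1 && iq2.size() == l2;
    std::string ms;
    std::vector<int> mq;
    ms.reserve(frag); mq.reserve(frag);
    for (int pos = 0; pos < frag; ++pos) {
      bool in1 = pos < l1, in2 = pos >= t;
      char c1 = in1 ? s1[pos] : 'N';
      char c2 = in2 ? rc2[pos - t] : 'N';
      int qa = in1 && have_q ? iq1[pos] : 0;
      int qb = in2 && have_q ? iq2[l2 - 1 - (pos - t)] : 0;  // q2 reversed
      if (in1 && in2) {
        if (c1 == c2) { ms.push_back(c1); mq.push_back(std::max(qa, qb)); }
        else if (qa >= qb) { ms.push_back(c1); mq.push_back(qa - qb); }
        else { ms.push_back(c2); mq.push_back(qb - qa); }
      } else if (in1) { ms.push_back(c1); mq.push_back(qa); }
      else { ms.push_back(c2); mq.push_back(qb); }
    }
    mseq[i] = ms;
    mqual[i] = wrap(mq);
    merged[i] = true;
  }
  return List::create(_["seq"] = mseq, _["qual"] = mqual, _["merged"] = merged,
                      _["overlap"] = overlap, _["mismatches"] = mismatches,
                      _["shift"] = shift);
}

// ---------------------------------------------------------------------------
// k-mer hit counting for coverage tracks (2-bit rolling hash, k <= 31)
// ---------------------------------------------------------------------------

static inline uint64_t rc_hash(uint64_t h, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) { r = (r << 2) | (3ULL - (h & 3ULL)); h >>= 2; }
  return r;
}

// Multiplicity, in `reads`, of each k-mer of `target`. NA for target k-mers
// containing non-ACGT characters.
// [[Rcpp::export]]
IntegerVector cpp_kmer_hit_counts(std::string target, CharacterVector reads,
                                  int k, bool canonical) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  uint64_t mask = (1ULL << (2 * k)) - 1;
  std::unordered_map<uint64_t, int> counts;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    uint64_t key = 0; int run = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int c = base_code(s[p]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t) c) & mask;
      if (++run >= k) {
        uint64_t h = key;
        if (canonical) { uint64_t r = rc_hash(key, k); if (r < h) h = r; }
        ++counts[h];
      }
    }
  }
  int Lt = (int) target.size();
  int nk = Lt - k + 1;
  if (nk < 1) return IntegerVector(0);
  IntegerVector out(nk, NA_INTEGER);
  std::vector<int8_t> t = encode(target);
  uint64_t key = 0; int run = 0;
  for (int p = 0; p < Lt; ++p) {
    if (t[p] < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t) t[p]) & mask;
    if (++run >= k) {
      uint64_t h = key;
      if (canonical) { uint64_t r = rc_hash(key, k); if (r < h) h = r; }
      auto it = counts.find(h);
      out[p - k + 1] = it == counts.end() ? 0 : it->second;
    }
  }
  return out;
}

// In-place style substitution application for the read simulator: replace the
// base at pos[j] (1-based) of seqs[idx[j]] by one of its three alternatives,
// selected by alt[j] in 0..2.
// [[Rcpp::export]]
CharacterVector cpp_apply_subs(CharacterVector seqs, IntegerVector idx,
                               IntegerVector pos, IntegerVector alt) {
  static const char* bases = "ACGT";
  std::vector<std::string> s(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) s[i] = as<std::string>(seqs[i]);
  for (R_xlen_t j = 0; j < idx.size(); ++j) {
    std::string& sq = s[idx[j] - 1];
    int p = pos[j] - 1;
    if (p < 0 || p >= (int) sq.size()) continue;
    int orig = base_code(sq[p]);
    if (orig < 0) continue;
    int a = alt[j] % 3;
    int nb = (orig + 1 + a) % 4;
    sq[p] = bases[nb];
  }
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) out[i] = s[i];
  return out;
}
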
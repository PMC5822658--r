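#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// ---- shared helpers ---------------------------------------------------

static std::vector<int> encode_seq(const std::string& s,
                                   const std::string& alphabet) {
  int lut[256];
  std::fill(lut, lut + 256, -1);
  for (size_t i = 0; i < alphabet.size(); ++i)
    lut[(unsigned char)alphabet[i]] = (int)i;
  int xi = lut[(unsigned char)'X'] >= 0 ? lut[(unsigned char)'X'] : 0;
  std::vector<int> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int v = lut[(unsigned char)s[i]];
    out[i] = v >= 0 ? v : xi;
  }
  return out;
}

// ---- translated search: seeded, X-drop-triggered local alignment ------

struct SwHit {
  int qstart, qend, sstart, send, score, matches, alen;
};

// Affine-gap Smith-Waterman with traceback; gap of length L costs
// -(gap_open + (L-1)*gap_extend), gap_open/gap_extend given as negative
// scores. Returns best local alignment (score 0 => no hit).
static bool smith_waterman(const std::vector<int>& q, const std::vector<int>& s,
                           const IntegerMatrix& mat, int go, int ge,
                           SwHit& hit) {
  const int m = (int)q.size(), n = (int)s.size();
  const int NEG = -1000000000;
  // DP matrices (row-major, (m+1) x (n+1))
  std::vector<int> M((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> Ix((size_t)(m + 1) * (n + 1), NEG); // gap in subject (up)
  std::vector<int> Iy((size_t)(m + 1) * (n + 1), NEG); // gap in query (left)
  std::vector<unsigned char> tbM((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbX((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbY((size_t)(m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const size_t row = (size_t)i * (n + 1), prow = (size_t)(i - 1) * (n + 1);
    for (int j = 1; j <= n; ++j) {
      int ix1 = M[prow + j] + go, ix2 = Ix[prow + j] + ge;
      Ix[row + j] = ix1 >= ix2 ? ix1 : ix2;
      tbX[row + j] = ix1 >= ix2 ? 0 : 1;
      int iy1 = M[row + j - 1] + go, iy2 = Iy[row + j - 1] + ge;
      Iy[row + j] = iy1 >= iy2 ? iy1 : iy2;
      tbY[row + j] = iy1 >= iy2 ? 0 : 1;
      int sc = mat(q[i - 1], s[j - 1]);
      int d = M[prow + j - 1] + sc;
      int v = d; unsigned char t = 1; // 1=from M, 2=from Ix, 3=from Iy
      if (Ix[prow + j - 1] + sc > v) { v = Ix[prow + j - 1] + sc; t = 2; }
      if (Iy[prow + j - 1] + sc > v) { v = Iy[prow + j - 1] + sc; t = 3; }
      if (v <= 0) { v = 0; t = 0; }
      M[row + j] = v; tbM[row + j] = t;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (best <= 0) return false;
  // traceback from (bi, bj) in M state
  int i = bi, j = bj, state = 0; // 0=M, 1=Ix, 2=Iy
  int matches = 0, alen = 0;
  int qe = bi, se = bj;
  while (i > 0 && j > 0) {
    size_t row = (size_t)i * (n + 1);
    if (state == 0) {
      unsigned char t = tbM[row + j];
      if (t == 0) break;
      alen++;
      if (q[i - 1] == s[j - 1]) matches++;
      state = (t == 1) ? 0 : (t == 2 ? 1 : 2);
      --i; --j;
    } else if (state == 1) { // Ix: gap in subject, consume query row
      unsigned char t = tbX[row + j];
      alen++;
      --i;
      state = (t == 0) ? 0 : 1;
    } else { // Iy: gap in query, consume subject column
      unsigned char t = tbY[row + j];
      alen++;
      --j;
      state = (t == 0) ? 0 : 2;
    }
  }
  hit.qstart = i; hit.qend = qe; hit.sstart = j; hit.send = se;
  hit.score = best; hit.matches = matches; hit.alen = alen;
  return true;
}

// [[Rcpp::export]]
List cpp_smith_waterman(std::string query, std::string subject,
                        IntegerMatrix submat, std::string alphabet,
                        int gap_open, int gap_extend) {
  std::vector<int> q = encode_seq(query, alphabet);
  std::vector<int> s = encode_seq(subject, alphabet);
  SwHit h;
  if (!smith_waterman(q, s, submat, gap_open, gap_extend, h))
    return List::create(Named("score") = 0);
  return List::create(Named("score") = h.score,
                      Named("qstart") = h.qstart, Named("qend") = h.qend,
                      Named("sstart") = h.sstart, Named("send") = h.send,
                      Named("matches") = h.matches,
                      Named("align_length") = h.alen);
}

// Seeded search of one protein query against one frame translation.
// Exact word_size-mer seeds, ungapped X-drop extension as trigger, then
// gapped Smith-Waterman in a window around each candidate region.
// [[Rcpp::export]]
DataFrame cpp_search_frame(std::string query, std::string subject,
                           IntegerMatrix submat, std::string alphabet,
                           int word_size, int gap_open, int gap_extend,
                           int x_drop, int trigger) {
  std::vector<int> q = encode_seq(query, alphabet);
  std::vector<int> s = encode_seq(subject, alphabet);
  const int m = (int)q.size(), n = (int)s.size();
  std::vector<int> qs, qe, ss, se, sc, mt, al;
  if (m < word_size || n < word_size) {
    return DataFrame::create(Named("qstart") = qs, Named("qend") = qe,
                             Named("sstart") = ss, Named("send") = se,
                             Named("score") = sc, Named("matches") = mt,
                             Named("align_length") = al);
  }
  const int A = (int)alphabet.size();
  // index query words
  std::unordered_map<long, std::vector<int> > widx;
  for (int i = 0; i + word_size <= m; ++i) {
    long key = 0;
    for (int k = 0; k < word_size; ++k) key = key * A + q[i + k];
    widx[key].push_back(i);
  }
  std::unordered_map<long long, int> reached; // per-diagonal right extent
  std::vector<std::pair<int, int> > regions;
  for (int j = 0; j + word_size <= n; ++j) {
    long key = 0;
    for (int k = 0; k < word_size; ++k) key = key * A + s[j + k];
    auto it = widx.find(key);
    if (it == widx.end()) continue;
    for (int qi : it->second) {
      long long diag = (long long)j - qi + m; // shifted to be positive-ish
      auto rit = reached.find(diag);
      if (rit != reached.end() && j < rit->second) continue;
      // ungapped extension
      int sc0 = 0;
      for (int k = 0; k < word_size; ++k) sc0 += submat(q[qi + k], s[j + k]);
      int cur = sc0, bestr = sc0;
      int ri = qi + word_size, rj = j + word_size, bre = rj;
      while (ri < m && rj < n) {
        cur += submat(q[ri], s[rj]);
        if (cur > bestr) { bestr = cur; bre = rj + 1; }
        if (bestr - cur > x_drop) break;
        ++ri; ++rj;
      }
      int total = bestr, bls = j;
      cur = bestr;
      int li = qi - 1, lj = j - 1;
      while (li >= 0 && lj >= 0) {
        cur += submat(q[li], s[lj]);
        if (cur > total) { total = cur; bls = lj; }
        if (total - cur > x_drop) break;
        --li; --lj;
      }
      reached[diag] = bre;
      if (total >= trigger) {
        int rs = bls - m - 10; if (rs < 0) rs = 0;
        int re = bre + m + 10; if (re > n) re = n;
        regions.push_back(std::make_pair(rs, re));
      }
    }
  }
  if (regions.empty()) {
    return DataFrame::create(Named("qstart") = qs, Named("qend") = qe,
                             Named("sstart") = ss, Named("send") = se,
                             Named("score") = sc, Named("matches") = mt,
                             Named("align_length") = al);
  }
  std::sort(regions.begin(), regions.end());
  std::vector<std::pair<int, int> > merged;
  for (auto& r : regions) {
    if (!merged.empty() && r.first <= merged.back().second)
      merged.back().second = std::max(merged.back().second, r.second);
    else merged.push_back(r);
  }
  for (auto& r : merged) {
    std::vector<int> sub(s.begin() + r.first, s.begin() + r.second);
    SwHit h;
    if (!smith_waterman(q, sub, submat, gap_open, gap_extend, h)) continue;
    qs.push_back(h.qstart); qe.push_back(h.qend);
    ss.push_back(h.sstart + r.first); se.push_back(h.send + r.first);
    sc.push_back(h.score); mt.push_back(h.matches); al.push_back(h.alen);
  }
  return DataFrame::create(Named("qstart") = qs, Named("qend") = qe,
                           Named("sstart") = ss, Named("send") = se,
                           Named("score") = sc, Named("matches") = mt,
                           Named("align_length") = al);
}

// ---- read mapper: k-mer index + full-read Hamming verification --------

static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector ref_seqs,
                        int k, int max_mismatches) {
  const int nc = ref_seqs.size();
  std::vector<std::string> refs(nc);
  std::vector<long long> offset(nc + 1, 0);
  for (int i = 0; i < nc; ++i) {
    refs[i] = as<std::string>(ref_seqs[i]);
    offset[i + 1] = offset[i] + (long long)refs[i].size();
  }
  std::string cat;
  cat.reserve((size_t)offset[nc]);
  for (int i = 0; i < nc; ++i) cat += refs[i];
  const long long N = (long long)cat.size();
  // index k-mers (skip windows containing non-ACGT)
  std::unordered_map<uint64_t, std::vector<uint32_t> > idx;
  idx.reserve((size_t)(N / 2 + 16));
  {
    uint64_t key = 0; int run = 0;
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (long long i = 0; i < N; ++i) {
      int b = base2bit(cat[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) idx[key].push_back((uint32_t)(i - k + 1));
    }
  }
  std::vector<int> out_read, out_contig, out_start, out_mm;
  std::vector<int> out_strand;
  const int nr = reads.size();
  GetRNGstate();
  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int L = (int)fwd.size();
    if (L < k) continue;
    std::string rev(L, 'N');
    for (int i = 0; i < L; ++i) {
      char c = fwd[L - 1 - i];
      rev[i] = (c == 'A') ? 'T' : (c == 'C') ? 'G' : (c == 'G') ? 'C'
               : (c == 'T') ? 'A' : 'N';
    }
    int best_mm = max_mismatches + 1;
    // candidates: (global start, strand)
    std::vector<std::pair<long long, int> > best_pl;
    std::vector<std::pair<long long, int> > seen;
    int anchors[3] = {0, (L - k) / 2, L - k};
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& rd = (strand == 0) ? fwd : rev;
      for (int a = 0; a < 3; ++a) {
        int off = anchors[a];
        if (off < 0) continue;
        uint64_t key = 0; bool ok = true;
        for (int t = 0; t < k; ++t) {
          int b = base2bit(rd[off + t]);
          if (b < 0) { ok = false; break; }
          key = (key << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        auto it = idx.find(key);
        if (it == idx.end()) continue;
        for (uint32_t hpos : it->second) {
          long long st = (long long)hpos - off;
          if (st < 0 || st + L > N) continue;
          std::pair<long long, int> cand(st, strand);
          if (std::find(seen.begin(), seen.end(), cand) != seen.end())
            continue;
          seen.push_back(cand);
          // must lie within a single contig
          int ci = (int)(std::upper_bound(offset.begin(), offset.end(), st)
                         - offset.begin()) - 1;
          if (st + L > offset[ci + 1]) continue;
          int mm = 0;
          for (int t = 0; t < L && mm < best_mm; ++t)
            if (cat[st + t] != rd[t] || cat[st + t] == 'N') ++mm;
          if (mm < best_mm) {
            best_mm = mm;
            best_pl.clear();
            best_pl.push_back(cand);
          } else if (mm == best_mm && mm <= max_mismatches) {
            best_pl.push_back(cand);
          }
        }
      }
    }
    if (best_mm <= max_mismatches && !best_pl.empty()) {
      int pick = 0;
      if (best_pl.size() > 1) {
        pick = (int)(unif_rand() * best_pl.size());
        if (pick >= (int)best_pl.size()) pick = (int)best_pl.size() - 1;
      }
      long long st = best_pl[pick].first;
      int ci = (int)(std::upper_bound(offset.begin(), offset.end(), st)
                     - offset.begin()) - 1;
      out_read.push_back(r + 1);
      out_contig.push_back(ci + 1);
      out_start.push_back((int)(st - offset[ci]));
      out_strand.push_back(best_pl[pick].second);
      out_mm.push_back(best_mm);
    }
  }
  PutRNGstate();
  return DataFrame::create(Named("read") = out_read,
                           Named("contig") = out_contig,
                           Named("start") = out_start,
                           Named("strand") = out_strand,
                           Named("mismatches") = out_mm);
}

// ---- terminal inverted repeat scan ------------------------------------

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

// Best (longest, then fewest mismatches, then leftmost) inverted repeat
// pair with the left repeat starting within the first `window` bp and
// the right repeat ending within the last `window` bp.
// [[Rcpp::export]]
List cpp_find_tirs(std::string seq, int min_len, int max_len,
                   int max_mismatch, int window) {
  const int L = (int)seq.size();
  if (L <= 2 * window) return List::create(Named("found") = false);
  for (int len = std::min(max_len, window); len >= min_len; --len) {
    int best_mm = max_mismatch + 1, best_a = -1, best_b = -1;
    for (int a = 0; a + len <= window; ++a) {
      for (int bend = L; bend >= L - window + len; --bend) {
        int b = bend - len;
        int mm = 0;
        for (int t = 0; t < len && mm <= max_mismatch; ++t) {
          if (seq[b + len - 1 - t] != comp_base(seq[a + t])) ++mm;
        }
        if (mm < best_mm) { best_mm = mm; best_a = a; best_b = b; }
        else if (mm == best_mm && best_a >= 0 &&
                 (a < best_a || (a == best_a && b < best_b))) {
          best_a = a; best_b = b;
        }
      }
    }
    if (best_mm <= max_mismatch) {
      return List::create(Named("found") = true,
                          Named("left_start") = best_a,
                          Named("left_end") = best_a + len,
                          Named("right_start") = best_b,
                          Named("right_end") = best_b + len,
                          Named("length") = len,
                          Named("mismatches") = best_mm);
    }
  }
  return List::create(Named("found") = false);
}
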
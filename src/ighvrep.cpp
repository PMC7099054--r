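#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// paired-end overlap merging
// ---------------------------------------------------------------------------

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) c = comp_base(c);
  return out;
}

// Merge read pairs. read2/qual2 are as sequenced (reverse strand); they are
// reverse-complemented (qualities reversed) before the overlap search.
// The overlap offset minimizing the mismatch ratio is chosen (ties -> longest
// overlap); disagreeing overlap bases take the higher-quality call.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector read1, CharacterVector read2,
                     CharacterVector qual1, CharacterVector qual2,
                     int min_overlap, double max_mismatch_ratio) {
  int n = read1.size();
  CharacterVector seq(n), status(n);
  IntegerVector ov_len(n), ov_mism(n);
  NumericVector ratio(n);
  for (int r = 0; r < n; ++r) {
    std::string s1 = as<std::string>(read1[r]);
    std::string q1 = as<std::string>(qual1[r]);
    std::string s2 = revcomp(as<std::string>(read2[r]));
    std::string q2 = as<std::string>(qual2[r]);
    std::reverse(q2.begin(), q2.end());
    int l1 = (int)s1.size(), l2 = (int)s2.size();
    int maxov = std::min(l1, l2);
    int best_ov = 0, best_mism = 0;
    bool have = false;
    for (int ov = 1; ov <= maxov; ++ov) {
      // suffix of s1 vs prefix of s2
      int mism = 0;
      bool viable = true;
      for (int i = 0; i < ov; ++i) {
        if (s1[l1 - ov + i] != s2[i]) {
          ++mism;
          // cannot beat (or tie, which prefers longer == current later ov)
          if (have && (long long)mism * best_ov > (long long)best_mism * ov) {
            viable = false;
            break;
          }
        }
      }
      if (!viable) continue;
      if (!have || (long long)mism * best_ov <= (long long)best_mism * ov) {
        best_ov = ov; best_mism = mism; have = true;
      }
    }
    double rat = best_ov > 0 ? (double)best_mism / best_ov : 1.0;
    ov_len[r] = best_ov; ov_mism[r] = best_mism; ratio[r] = rat;
    if (best_ov < min_overlap) {
      status[r] = "short_overlap"; seq[r] = NA_STRING;
    } else if (rat >= max_mismatch_ratio) {
      status[r] = "high_mismatch"; seq[r] = NA_STRING;
    } else {
      std::string merged = s1;
      for (int i = 0; i < best_ov; ++i) {
        int p1 = l1 - best_ov + i;
        if (s1[p1] != s2[i] && q2[i] > q1[p1]) merged[p1] = s2[i];
      }
      merged += s2.substr(best_ov);
      seq[r] = merged; status[r] = "merged";
    }
  }
  return List::create(_["sequence"] = seq, _["overlap_len"] = ov_len,
                      _["mismatches"] = ov_mism, _["mismatch_ratio"] = ratio,
                      _["status"] = status);
}

// ---------------------------------------------------------------------------
// germline V assignment: 13-mer seed-and-vote candidate filter, then
// diagonal evaluation with banded affine-gap DP fallback.
// Scoring: match +1, mismatch -1, gap open -4, gap extend -1.
// Alignment is global in the germline allele, local in the contig.
// ---------------------------------------------------------------------------

static inline int base2bit(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; default: return -1; }
}

struct AlnResult {
  int score = INT_MIN;
  int mismatches = 0;
  int gap_events = 0;
  int v_end = 0;          // 0-based exclusive end of the V in the contig
  std::string v_obs;      // observed bases over allele coordinates ('-' gap)
  bool ok = false;
};

// ungapped comparison of the full allele against the contig at offset d
static AlnResult diag_align(const std::string& contig, const std::string& al,
                            int d) {
  AlnResult res;
  int alen = (int)al.size();
  if (d < 0 || d + alen > (int)contig.size()) return res;
  int mism = 0;
  std::string obs(alen, 'N');
  for (int i = 0; i < alen; ++i) {
    obs[i] = contig[d + i];
    if (contig[d + i] != al[i]) ++mism;
  }
  res.score = alen - 2 * mism;
  res.mismatches = mism;
  res.v_end = d + alen;
  res.v_obs = obs;
  res.ok = true;
  return res;
}

static const int NEG = -1000000;

// banded affine DP around diagonal d0 with half-width `band`
static AlnResult banded_align(const std::string& contig, const std::string& al,
                              int d0, int band,
                              int match, int mismatch, int gopen, int gext) {
  int alen = (int)al.size(), clen = (int)contig.size();
  int W = 2 * band + 1;
  std::vector<std::vector<int>> M(alen + 1, std::vector<int>(W, NEG));
  std::vector<std::vector<int>> Dx = M, Dy = M;   // Dx: gap in contig, Dy: gap in allele
  std::vector<std::vector<int8_t>> tbM(alen + 1, std::vector<int8_t>(W, -1)),
      tbDx = tbM, tbDy = tbM;
  auto jpos = [&](int i, int c) { return i + d0 - band + c; };
  for (int c = 0; c < W; ++c) {
    int j = jpos(0, c);
    if (j >= 0 && j <= clen) M[0][c] = 0;  // free start in contig
  }
  for (int i = 1; i <= alen; ++i) {
    for (int c = 0; c < W; ++c) {
      int j = jpos(i, c);
      if (j < 1 || j > clen) { // need contig position j-1 for aligned state
        // Dx (contig stays) may still be valid if j in [0, clen]
        if (j >= 0 && j <= clen) {
          int fromM = M[i - 1][c + 1 < W ? c + 1 : c];
          int fromD = Dx[i - 1][c + 1 < W ? c + 1 : c];
          if (c + 1 < W) {
            if (fromM + gopen >= fromD + gext) { Dx[i][c] = fromM + gopen; tbDx[i][c] = 0; }
            else { Dx[i][c] = fromD + gext; tbDx[i][c] = 1; }
          }
        }
        continue;
      }
      int sc = (al[i - 1] == contig[j - 1]) ? match : mismatch;
      int bm = M[i - 1][c], bx = Dx[i - 1][c], by = Dy[i - 1][c];
      int best = bm; int8_t tb = 0;
      if (bx > best) { best = bx; tb = 1; }
      if (by > best) { best = by; tb = 2; }
      if (best > NEG) { M[i][c] = best + sc; tbM[i][c] = tb; }
      if (c + 1 < W) {
        int fromM = M[i - 1][c + 1], fromD = Dx[i - 1][c + 1];
        int vM = fromM > NEG ? fromM + gopen : NEG;
        int vD = fromD > NEG ? fromD + gext : NEG;
        if (vM >= vD) { if (vM > NEG) { Dx[i][c] = vM; tbDx[i][c] = 0; } }
        else { Dx[i][c] = vD; tbDx[i][c] = 1; }
      }
      if (c - 1 >= 0) {
        int fromM = M[i][c - 1], fromD = Dy[i][c - 1];
        int vM = fromM > NEG ? fromM + gopen : NEG;
        int vD = fromD > NEG ? fromD + gext : NEG;
        if (vM >= vD) { if (vM > NEG) { Dy[i][c] = vM; tbDy[i][c] = 0; } }
        else { Dy[i][c] = vD; tbDy[i][c] = 1; }
      }
    }
  }
  AlnResult res;
  int bc = -1;
  for (int c = 0; c < W; ++c) {
    int j = jpos(alen, c);
    if (j < 0 || j > clen) continue;
    if (M[alen][c] > res.score) { res.score = M[alen][c]; bc = c; }
  }
  if (bc < 0 || res.score <= NEG) return res;
  // traceback
  std::string obs(alen, '-');
  int i = alen, c = bc, state = 0;
  res.v_end = jpos(alen, bc);
  bool in_gap = false;
  while (i > 0) {
    int j = jpos(i, c);
    if (state == 0) {
      obs[i - 1] = contig[j - 1];
      if (contig[j - 1] != al[i - 1]) ++res.mismatches;
      int tb = tbM[i][c];
      in_gap = false;
      --i;
      state = tb;
    } else if (state == 1) { // Dx: allele position unmatched (deletion)
      obs[i - 1] = '-';
      if (!in_gap) ++res.gap_events;
      in_gap = tbDx[i][c] == 1;
      int tb = tbDx[i][c];
      --i; ++c;
      state = tb == 1 ? 1 : 0;
    } else { // Dy: extra contig base (insertion)
      if (!in_gap) ++res.gap_events;
      in_gap = tbDy[i][c] == 1;
      int tb = tbDy[i][c];
      --c;
      state = tb == 1 ? 2 : 0;
    }
  }
  res.v_obs = obs;
  res.ok = true;
  return res;
}

// [[Rcpp::export]]
List cpp_assign_v(CharacterVector contigs, CharacterVector allele_seqs,
                  int k = 13, int top_n = 3, int band = 5,
                  double min_identity = 0.70, int min_aln_len = 100,
                  int match = 1, int mismatch = -1,
                  int gap_open = -4, int gap_ext = -1) {
  int n_al = allele_seqs.size();
  std::vector<std::string> als(n_al);
  for (int a = 0; a < n_al; ++a) als[a] = as<std::string>(allele_seqs[a]);

  // k-mer index over alleles
  std::unordered_map<uint32_t, std::vector<std::pair<int, int>>> index;
  uint32_t mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xFFFFFFFFu;
  for (int a = 0; a < n_al; ++a) {
    const std::string& s = als[a];
    uint32_t key = 0; int run = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint32_t)b) & mask;
      if (++run >= k) index[key].push_back({a, i - k + 1});
    }
  }

  int n = contigs.size();
  IntegerVector v_idx(n), score(n), mism(n), gaps(n), v_end(n);
  NumericVector identity(n);
  CharacterVector v_obs(n);
  LogicalVector assigned(n);

  std::vector<std::unordered_map<int, int>> votes(n_al);
  for (int r = 0; r < n; ++r) {
    std::string ctg = as<std::string>(contigs[r]);
    for (auto& m : votes) m.clear();
    uint32_t key = 0; int run = 0;
    for (int i = 0; i < (int)ctg.size(); ++i) {
      int b = base2bit(ctg[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint32_t)b) & mask;
      if (++run >= k) {
        auto it = index.find(key);
        if (it == index.end()) continue;
        int cpos = i - k + 1;
        for (auto& hit : it->second) votes[hit.first][cpos - hit.second]++;
      }
    }
    // best diagonal + vote count per allele
    std::vector<std::tuple<int, int, int>> cand;  // (-votes, allele, diag)
    for (int a = 0; a < n_al; ++a) {
      int bestd = 0, bestv = 0;
      for (auto& kv : votes[a])
        if (kv.second > bestv) { bestv = kv.second; bestd = kv.first; }
      if (bestv > 0) cand.push_back({-bestv, a, bestd});
    }
    std::sort(cand.begin(), cand.end());
    if ((int)cand.size() > top_n) cand.resize(top_n);

    int best_a = -1;
    AlnResult best;
    for (auto& c : cand) {
      int a = std::get<1>(c), d = std::get<2>(c);
      int nvotes = -std::get<0>(c);
      AlnResult res = diag_align(ctg, als[a], d);
      double ident = res.ok ?
        (double)((int)als[a].size() - res.mismatches) / als[a].size() : 0.0;
      // the ungapped diagonal is the alignment unless it cannot clear the
      // identity floor while the seed support says the homology is real
      // (e.g. an indel splitting the diagonal) -- then do banded DP
      if ((!res.ok || ident < min_identity) && nvotes >= 3) {
        AlnResult res2 = banded_align(ctg, als[a], d, band,
                                      match, mismatch, gap_open, gap_ext);
        if (res2.ok && (!res.ok || res2.score > res.score)) res = res2;
      }
      if (!res.ok) continue;
      bool better = res.score > best.score ||
        (res.score == best.score && res.mismatches < best.mismatches);
      if (best_a < 0 || better) { best = res; best_a = a; }
    }
    if (best_a >= 0) {
      int alen = (int)als[best_a].size();
      double ident = (double)(alen - best.mismatches - best.gap_events) / alen;
      if (ident >= min_identity && alen >= min_aln_len) {
        assigned[r] = true;
        v_idx[r] = best_a + 1;
        score[r] = best.score; mism[r] = best.mismatches;
        gaps[r] = best.gap_events; v_end[r] = best.v_end;
        identity[r] = ident; v_obs[r] = best.v_obs;
        continue;
      }
    }
    assigned[r] = false;
    v_idx[r] = NA_INTEGER; score[r] = NA_INTEGER; mism[r] = NA_INTEGER;
    gaps[r] = NA_INTEGER; v_end[r] = NA_INTEGER;
    identity[r] = NA_REAL; v_obs[r] = NA_STRING;
  }
  return List::create(_["assigned"] = assigned, _["v_idx"] = v_idx,
                      _["score"] = score, _["mismatches"] = mism,
                      _["gap_events"] = gaps, _["v_end"] = v_end,
                      _["identity"] = identity, _["v_obs"] = v_obs);
}

// Hamming distance between equal-length strings (utility for clustering and
// oracles); returns -1 for unequal lengths.
// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b) {
  int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string x = as<std::string>(a[i]), y = as<std::string>(b[i]);
    if (x.size() != y.size()) { out[i] = -1; continue; }
    int d = 0;
    for (size_t j = 0; j < x.size(); ++j) if (x[j] != y[j]) ++d;
    out[i] = d;
  }
  return out;
}
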
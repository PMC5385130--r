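// Seeded local alignment engine: k-mer seeding, diagonal clustering, banded
// affine Smith-Waterman with traceback, plus an exhaustive full-matrix DP
// used as the exact method. Scores are integer; gap of length L costs
// -(gap_open + L * gap_ext) with gap_open, gap_ext <= 0 (BLAST convention).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const int NEG_INF = -100000000;

struct AlnResult {
  int score = NEG_INF;
  int qs = 0, qe = 0, ss = 0, se = 0;  // 0-based half-open
  int matches = 0, mismatches = 0, gapopens = 0, alen = 0;
  bool valid = false;
};

// Encode a sequence against an alphabet; unknown characters map to `wild`.
static std::vector<int8_t> encode(const std::string &seq,
                                  const std::string &alphabet, int wild) {
  int8_t lut[256];
  std::fill(lut, lut + 256, (int8_t)wild);
  for (size_t i = 0; i < alphabet.size(); ++i) {
    unsigned char c = (unsigned char)alphabet[i];
    lut[c] = (int8_t)i;
    lut[std::tolower(c)] = (int8_t)i;
  }
  std::vector<int8_t> out(seq.size());
  for (size_t i = 0; i < seq.size(); ++i)
    out[i] = lut[(unsigned char)seq[i]];
  return out;
}

// Banded affine local alignment on encoded sequences. Cells with diagonal
// j - i outside [dlo, dhi] are skipped (treated as empty). Traceback is kept
// for the whole (m+1) x (n+1) matrix, so callers pass windows, not whole
// genomes, when banding around seeds.
static AlnResult sw_band(const int8_t *q, int m, const int8_t *s, int n,
                         const int *sub, int ncode, int wild,
                         int gap_open, int gap_ext, int dlo, int dhi) {
  AlnResult res;
  if (m == 0 || n == 0) return res;
  const int go = gap_open + gap_ext;  // cost of first gapped column
  const int ge = gap_ext;
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Fcol(n + 1, NEG_INF);
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i + dlo), jhi = std::min(n, i + dhi);
    std::fill(Hcur.begin(), Hcur.end(), 0);
    int E = NEG_INF;
    if (jlo > jhi) { std::swap(Hprev, Hcur); continue; }
    for (int j = jlo; j <= jhi; ++j) {
      size_t t = (size_t)i * (n + 1) + j;
      uint8_t code = 0;
      // E: gap in query (consumes subject)
      int e_open = Hcur[j - 1] + go, e_ext = E + ge;
      E = std::max(e_open, e_ext);
      if (e_ext > e_open) code |= 4;
      // F: gap in subject (consumes query)
      int f_open = Hprev[j] + go, f_ext = Fcol[j] + ge;
      int F = std::max(f_open, f_ext);
      if (f_ext > f_open) code |= 8;
      Fcol[j] = F;
      int diag = Hprev[j - 1] + sub[(int)q[i - 1] * ncode + (int)s[j - 1]];
      int h = 0; uint8_t dir = 0;
      if (diag > h) { h = diag; dir = 1; }
      if (E > h)    { h = E;    dir = 2; }
      if (F > h)    { h = F;    dir = 3; }
      Hcur[j] = h;
      tb[t] = code | dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    // reset F outside the band for the next row
    if (jlo > 1) Fcol[jlo - 1] = NEG_INF;
    std::swap(Hprev, Hcur);
  }
  if (best <= 0) return res;
  // traceback
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
  res.score = best; res.qe = bi; res.se = bj;
  while (i > 0 && j > 0) {
    uint8_t t = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      int dir = t & 3;
      if (dir == 0) break;
      if (dir == 1) {
        ++res.alen;
        bool match = (q[i - 1] == s[j - 1]) && q[i - 1] != wild && s[j - 1] != wild;
        if (match) ++res.matches; else ++res.mismatches;
        --i; --j;
      } else if (dir == 2) state = 1;
      else state = 2;
    } else if (state == 1) {  // E: gap in query, consume subject
      ++res.alen;
      bool ext = (t & 4) != 0;
      if (!ext) { ++res.gapopens; state = 0; }
      --j;
      // re-read code from the cell we just consumed is already done: the
      // open/extend bit of cell (i, j+1) told us whether to leave E state.
    } else {  // F: gap in subject, consume query
      ++res.alen;
      bool ext = (t & 8) != 0;
      if (!ext) { ++res.gapopens; state = 0; }
      --i;
    }
  }
  res.qs = i; res.ss = j;
  res.valid = true;
  return res;
}

// ---- k-mer seeding -------------------------------------------------------

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

static void index_kmers(const std::vector<int8_t> &s, int k, int wild,
                        KmerIndex &idx) {
  int n = (int)s.size();
  if (n < k) return;
  uint64_t key = 0, mask = (k >= 13) ? ~0ULL : ((1ULL << (5 * k)) - 1);
  int run = 0;  // valid symbols accumulated
  for (int j = 0; j < n; ++j) {
    if (s[j] == wild) { run = 0; key = 0; continue; }
    key = ((key << 5) | (uint64_t)s[j]) & mask;
    if (++run >= k) idx[key].push_back(j - k + 1);
  }
}

struct DiagCluster { int dlo, dhi, count; };

static std::vector<DiagCluster> seed_clusters(const std::vector<int8_t> &q,
                                              const KmerIndex &idx, int k,
                                              int wild, int merge_gap) {
  std::vector<int> diags;
  int m = (int)q.size();
  uint64_t key = 0, mask = (k >= 13) ? ~0ULL : ((1ULL << (5 * k)) - 1);
  int run = 0;
  for (int i = 0; i < m; ++i) {
    if (q[i] == wild) { run = 0; key = 0; continue; }
    key = ((key << 5) | (uint64_t)q[i]) & mask;
    if (++run >= k) {
      KmerIndex::const_iterator it = idx.find(key);
      if (it != idx.end()) {
        int qpos = i - k + 1;
        for (size_t z = 0; z < it->second.size(); ++z)
          diags.push_back(it->second[z] - qpos);
      }
    }
  }
  std::vector<DiagCluster> out;
  if (diags.empty()) return out;
  std::sort(diags.begin(), diags.end());
  DiagCluster cur; cur.dlo = diags[0]; cur.dhi = diags[0]; cur.count = 1;
  for (size_t z = 1; z < diags.size(); ++z) {
    if (diags[z] - cur.dhi <= merge_gap) { cur.dhi = diags[z]; ++cur.count; }
    else { out.push_back(cur); cur.dlo = diags[z]; cur.dhi = diags[z]; cur.count = 1; }
  }
  out.push_back(cur);
  // biggest clusters first; ties by diagonal for determinism
  std::stable_sort(out.begin(), out.end(),
                   [](const DiagCluster &a, const DiagCluster &b) {
                     if (a.count != b.count) return a.count > b.count;
                     return a.dlo < b.dlo;
                   });
  return out;
}

// Align query against subject around one seed cluster (window extraction).
static AlnResult align_cluster(const std::vector<int8_t> &q,
                               const std::vector<int8_t> &s,
                               const DiagCluster &c, int band_pad,
                               const int *sub, int ncode, int wild,
                               int gap_open, int gap_ext) {
  int m = (int)q.size(), n = (int)s.size();
  int dlo = c.dlo - band_pad, dhi = c.dhi + band_pad;
  int ws = std::max(0, dlo), we = std::min(n, m + dhi);
  AlnResult r;
  if (we <= ws) return r;
  r = sw_band(q.data(), m, s.data() + ws, we - ws, sub, ncode, wild,
              gap_open, gap_ext, dlo - ws, dhi - ws);
  if (r.valid) { r.ss += ws; r.se += ws; }
  return r;
}

// Deterministic preference order between candidate alignments of one pair:
// score, then identity, then alignment length.
static bool better_hit(const AlnResult &a, const AlnResult &b) {
  if (!b.valid) return a.valid;
  if (!a.valid) return false;
  if (a.score != b.score) return a.score > b.score;
  double ia = (double)a.matches / a.alen, ib = (double)b.matches / b.alen;
  if (ia != ib) return ia > ib;
  return a.alen > b.alen;
}

static AlnResult seeded_best(const std::vector<int8_t> &q,
                             const std::vector<int8_t> &s,
                             const KmerIndex &idx, int k,
                             const int *sub, int ncode, int wild,
                             int gap_open, int gap_ext, int band_pad,
                             int max_clusters) {
  AlnResult best;
  std::vector<DiagCluster> cl = seed_clusters(q, idx, k, wild, band_pad);
  int lim = std::min((int)cl.size(), max_clusters);
  for (int z = 0; z < lim; ++z) {
    AlnResult r = align_cluster(q, s, cl[z], band_pad, sub, ncode, wild,
                                gap_open, gap_ext);
    if (better_hit(r, best)) best = r;
  }
  return best;
}

static List result_to_list(const AlnResult &r) {
  if (!r.valid) return R_NilValue;
  return List::create(
    _["score"] = r.score, _["matches"] = r.matches,
    _["mismatches"] = r.mismatches, _["gapopens"] = r.gapopens,
    _["alen"] = r.alen,
    _["qstart"] = r.qs + 1, _["qend"] = r.qe,
    _["sstart"] = r.ss + 1, _["send"] = r.se);
}

// [[Rcpp::export]]
List sw_align_cpp(std::string q, std::string s, IntegerMatrix sub,
                  std::string alphabet, int wild, int gap_open, int gap_ext) {
  std::vector<int8_t> qc = encode(q, alphabet, wild);
  std::vector<int8_t> sc = encode(s, alphabet, wild);
  AlnResult r = sw_band(qc.data(), (int)qc.size(), sc.data(), (int)sc.size(),
                        sub.begin(), sub.nrow(), wild, gap_open, gap_ext,
                        -(int)qc.size() - 1, (int)sc.size() + 1);
  return result_to_list(r);
}

// [[Rcpp::export]]
List seeded_align_cpp(std::string q, std::string s, IntegerMatrix sub,
                      std::string alphabet, int wild, int gap_open,
                      int gap_ext, int k, int band_pad, int max_clusters) {
  std::vector<int8_t> qc = encode(q, alphabet, wild);
  std::vector<int8_t> sc = encode(s, alphabet, wild);
  KmerIndex idx;
  index_kmers(sc, k, wild, idx);
  AlnResult r = seeded_best(qc, sc, idx, k, sub.begin(), sub.nrow(), wild,
                            gap_open, gap_ext, band_pad, max_clusters);
  return result_to_list(r);
}

// All-pairs alignment of two gene sets; one row per (query, subject) pair
// with a positive-scoring alignment. exact = full-matrix DP (no seeding).
// [[Rcpp::export]]
DataFrame all_pairs_cpp(CharacterVector queries, CharacterVector subjects,
                        IntegerMatrix sub, std::string alphabet, int wild,
                        int gap_open, int gap_ext, int k, int band_pad,
                        int max_clusters, bool exact) {
  int nq = queries.size(), ns = subjects.size();
  std::vector<std::vector<int8_t> > qc(nq), sc(ns);
  for (int i = 0; i < nq; ++i) qc[i] = encode(as<std::string>(queries[i]), alphabet, wild);
  for (int j = 0; j < ns; ++j) sc[j] = encode(as<std::string>(subjects[j]), alphabet, wild);
  std::vector<int> oq, os, score, matches, mism, gaps, alen, qs, qe, ss, se;
  const int *subp = sub.begin(); int ncode = sub.nrow();
  for (int j = 0; j < ns; ++j) {
    KmerIndex idx;
    if (!exact) index_kmers(sc[j], k, wild, idx);
    for (int i = 0; i < nq; ++i) {
      AlnResult r;
      if (exact)
        r = sw_band(qc[i].data(), (int)qc[i].size(), sc[j].data(),
                    (int)sc[j].size(), subp, ncode, wild, gap_open, gap_ext,
                    -(int)qc[i].size() - 1, (int)sc[j].size() + 1);
      else
        r = seeded_best(qc[i], sc[j], idx, k, subp, ncode, wild,
                        gap_open, gap_ext, band_pad, max_clusters);
      if (r.valid) {
        oq.push_back(i + 1); os.push_back(j + 1); score.push_back(r.score);
        matches.push_back(r.matches); mism.push_back(r.mismatches);
        gaps.push_back(r.gapopens); alen.push_back(r.alen);
        qs.push_back(r.qs + 1); qe.push_back(r.qe);
        ss.push_back(r.ss + 1); se.push_back(r.se);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(
    _["query_idx"] = oq, _["subject_idx"] = os, _["score"] = score,
    _["matches"] = matches, _["mismatches"] = mism, _["gapopens"] = gaps,
    _["alen"] = alen, _["qstart"] = qs, _["qend"] = qe,
    _["sstart"] = ss, _["send"] = se);
}

static std::string revcomp_str(const std::string &s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) {
    switch (std::toupper(out[i])) {
      case 'A': out[i] = 'T'; break; case 'C': out[i] = 'G'; break;
      case 'G': out[i] = 'C'; break; case 'T': out[i] = 'A'; break;
      default:  out[i] = 'N';
    }
  }
  return out;
}

// Map reads/fragments against a set of reference contigs (both strands).
// Returns the best qualifying hit per read (identity >= min_identity,
// aligned read fraction >= min_cov) plus, per read x reference genome, the
// maximum identity over all qualifying candidates (for threshold sweeps).
// ref_id maps each contig to its genome (1-based); n_refs genomes total.
// [[Rcpp::export]]
List map_reads_cpp(CharacterVector reads, CharacterVector contigs,
                   IntegerVector ref_id, int n_refs, IntegerMatrix sub,
                   std::string alphabet, int wild, int gap_open, int gap_ext,
                   int k, int band_pad, int max_clusters,
                   double min_identity, double min_cov) {
  int nr = reads.size(), nc = contigs.size();
  std::vector<std::vector<int8_t> > cc(nc);
  std::vector<KmerIndex> idx(nc);
  for (int j = 0; j < nc; ++j) {
    cc[j] = encode(as<std::string>(contigs[j]), alphabet, wild);
    index_kmers(cc[j], k, wild, idx[j]);
  }
  const int *subp = sub.begin(); int ncode = sub.nrow();
  IntegerVector best_ref(nr, NA_INTEGER), best_contig(nr, NA_INTEGER),
      b_score(nr, NA_INTEGER), b_alen(nr, NA_INTEGER),
      b_sstart(nr, NA_INTEGER), b_send(nr, NA_INTEGER),
      b_mism(nr, NA_INTEGER), b_gaps(nr, NA_INTEGER);
  NumericVector b_ident(nr, NA_REAL);
  CharacterVector b_strand(nr, NA_STRING);
  NumericMatrix max_ident(nr, n_refs);
  std::fill(max_ident.begin(), max_ident.end(), NA_REAL);
  for (int i = 0; i < nr; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    std::string rev = revcomp_str(fwd);
    int rlen = (int)fwd.size();
    AlnResult best; int bref = -1, bcontig = -1; char bstrand = '+';
    for (int strand = 0; strand < 2; ++strand) {
      std::vector<int8_t> qc = encode(strand == 0 ? fwd : rev, alphabet, wild);
      for (int j = 0; j < nc; ++j) {
        std::vector<DiagCluster> cl = seed_clusters(qc, idx[j], k, wild, band_pad);
        int lim = std::min((int)cl.size(), max_clusters);
        for (int z = 0; z < lim; ++z) {
          AlnResult r = align_cluster(qc, cc[j], cl[z], band_pad, subp, ncode,
                                      wild, gap_open, gap_ext);
          if (!r.valid) continue;
          double ident = 100.0 * r.matches / r.alen;
          double cov = (double)(r.qe - r.qs) / rlen;
          if (cov < min_cov || ident < min_identity) continue;
          int g = ref_id[j] - 1;
          if (NumericVector::is_na(max_ident(i, g)) || ident > max_ident(i, g))
            max_ident(i, g) = ident;
          if (better_hit(r, best)) {
            best = r; bref = ref_id[j]; bcontig = j + 1;
            bstrand = (strand == 0) ? '+' : '-';
          }
        }
      }
    }
    if (best.valid) {
      best_ref[i] = bref; best_contig[i] = bcontig;
      b_score[i] = best.score; b_alen[i] = best.alen;
      b_ident[i] = 100.0 * best.matches / best.alen;
      b_sstart[i] = best.ss + 1; b_send[i] = best.se;
      b_mism[i] = best.mismatches; b_gaps[i] = best.gapopens;
      b_strand[i] = std::string(1, bstrand);
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  DataFrame hits = DataFrame::create(
    _["ref"] = best_ref, _["contig_idx"] = best_contig,
    _["strand"] = b_strand, _["score"] = b_score,
    _["identity"] = b_ident, _["alen"] = b_alen,
    _["mismatches"] = b_mism, _["gapopens"] = b_gaps,
    _["sstart"] = b_sstart, _["send"] = b_send,
    _["stringsAsFactors"] = false);
  return List::create(_["hits"] = hits, _["max_identity"] = max_ident);
}
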
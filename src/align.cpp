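#include <Rcpp.h>
#include <array>
#include <string>
#include <vector>

using namespace Rcpp;

// Exhaustive ungapped alignment of each read against every offset of every
// reference. For one read, placements achieving the minimum mismatch count
// are kept when that count is <= max_mismatch_frac * read length. Returns a
// long table indexed by position of the read in `reads` (1-based).
// [[Rcpp::export(name = ".align_ungapped_cpp")]]
DataFrame align_ungapped_cpp(CharacterVector reads, CharacterVector refs,
                             double max_mismatch_frac) {
  const int n_refs = refs.size();
  std::vector<std::string> refstr(n_refs);
  for (int j = 0; j < n_refs; ++j) refstr[j] = as<std::string>(refs[j]);

  std::vector<int> out_read, out_ref, out_start, out_mm;
  std::vector<std::string> out_mmpos;

  for (int i = 0; i < reads.size(); ++i) {
    const std::string rd = as<std::string>(reads[i]);
    const int L = (int)rd.size();
    if (L == 0) continue;
    const int allowed = (int)std::floor(max_mismatch_frac * L + 1e-9);
    int best = allowed + 1;
    std::vector<std::array<int, 3>> hits;  // ref index, start, mismatches
    for (int j = 0; j < n_refs; ++j) {
      const std::string &rf = refstr[j];
      const int maxoff = (int)rf.size() - L;
      for (int off = 0; off <= maxoff; ++off) {
        int mm = 0;
        bool bail = false;
        for (int k = 0; k < L; ++k) {
          if (rd[k] != rf[off + k] && ++mm > best) { bail = true; break; }
        }
        if (bail) continue;
        if (mm < best) { best = mm; hits.clear(); }
        hits.push_back({j, off, mm});
      }
    }
    if (best > allowed) continue;
    for (const auto &h : hits) {
      out_read.push_back(i + 1);
      out_ref.push_back(h[0] + 1);
      out_start.push_back(h[1]);
      out_mm.push_back(h[2]);
      std::string pos;
      if (h[2] > 0) {
        const std::string &rf = refstr[h[0]];
        for (int k = 0; k < L; ++k) {
          if (rd[k] != rf[h[1] + k]) {
            if (!pos.empty()) pos += ",";
            pos += std::to_string(h[1] + k);
          }
        }
      }
      out_mmpos.push_back(pos);
    }
  }

  return DataFrame::create(
      _["read_index"] = out_read, _["ref_index"] = out_ref,
      _["ref_start"] = out_start, _["n_mismatch"] = out_mm,
      _["mismatch_positions"] = out_mmpos,
      _["stringsAsFactors"] = false);
}

// Weighted base/stop pileup. One entry per alignment: the read sequence (as
// placed), the 1-based reference index, the 0-based start on the reference,
// and the fractional weight. Returns, per reference, a 5 x L count matrix
// (A, C, G, T, stop).
// [[Rcpp::export(name = ".pileup_cpp")]]
List pileup_cpp(CharacterVector seqs, IntegerVector ref_index,
                IntegerVector ref_start, NumericVector weight,
                IntegerVector ref_len) {
  const int n_refs = ref_len.size();
  std::vector<NumericMatrix> mats;
  mats.reserve(n_refs);
  for (int j = 0; j < n_refs; ++j) mats.emplace_back(5, ref_len[j]);

  for (int i = 0; i < seqs.size(); ++i) {
    const std::string sq = as<std::string>(seqs[i]);
    const int j = ref_index[i] - 1;
    const int st = ref_start[i];
    const double w = weight[i];
    if (j < 0 || j >= n_refs) stop("alignment references unknown gene");
    if (st < 0 || st + (int)sq.size() > ref_len[j])
      stop("alignment outside reference bounds");
    NumericMatrix &m = mats[j];
    for (int k = 0; k < (int)sq.size(); ++k) {
      int row;
      switch (sq[k]) {
        case 'A': row = 0; break;
        case 'C': row = 1; break;
        case 'G': row = 2; break;
        case 'T': row = 3; break;
        default: continue;  // N and friends are not counted
      }
      m(row, st + k) += w;
    }
    // an alignment starting at st has 5'-most covered position st, recorded
    // as an RT stop signal at position st - 1
    if (st >= 1) m(4, st - 1) += w;
  }

  List out(n_refs);
  for (int j = 0; j < n_refs; ++j) out[j] = mats[j];
  return out;
}
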
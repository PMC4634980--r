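#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Semi-global alignment of a read against a reference under explicit costs:
// match 0, mismatch `mismatch_cost`, gap `ins_cost`/`del_cost` per base.
// The read is consumed end to end; reference overhangs on either side are
// free, so the read may be placed anywhere on the reference. Read bases that
// fall beyond a reference end are forced gaps; they keep their per-base gap
// cost in the DP but are rendered as soft clips (S) in the CIGAR.
//
// Among equal-cost end placements one is drawn uniformly with R's RNG (so
// set.seed() makes placement reproducible). Within a placement, traceback
// ties are broken by a fixed precedence (diagonal, then deletion, then
// insertion), which is deterministic.
//
// [[Rcpp::export]]
List cpp_align_semiglobal(std::string read, std::string ref,
                          double mismatch_cost, double ins_cost,
                          double del_cost) {
  const int m = read.size(), n = ref.size();
  if (m < 1 || n < 1) stop("read and reference must be non-empty");

  // full matrix kept for traceback; desk-scale reads make this cheap
  std::vector<std::vector<double> > D(m + 1, std::vector<double>(n + 1));
  for (int j = 0; j <= n; ++j) D[0][j] = 0.0;        // free reference prefix
  for (int i = 1; i <= m; ++i) {
    D[i][0] = D[i - 1][0] + ins_cost;                // read overhang at start
    for (int j = 1; j <= n; ++j) {
      double sub = D[i - 1][j - 1] +
        (read[i - 1] == ref[j - 1] ? 0.0 : mismatch_cost);
      double up = D[i - 1][j] + ins_cost;            // read base, ref gap
      double left = D[i][j - 1] + del_cost;          // ref base, read gap
      double best = sub;
      if (up < best) best = up;
      if (left < best) best = left;
      D[i][j] = best;
    }
  }

  // free reference suffix: best end column in the last row
  double best = D[m][0];
  for (int j = 1; j <= n; ++j) if (D[m][j] < best) best = D[m][j];
  std::vector<int> ties;
  for (int j = 0; j <= n; ++j) if (D[m][j] == best) ties.push_back(j);

  // secondary criterion: among equal-cost end placements keep those whose
  // traceback has the fewest mismatches, so representation ties (gapped vs
  // mismatch tail at equal cost) resolve to the canonical gapped form;
  // genuine repeat placements have identical op composition and remain tied
  auto count_mismatches = [&](int jend) {
    int i = m, j = jend, mm = 0;
    while (i > 0) {
      if (j == 0) { --i; continue; }
      bool eq = read[i - 1] == ref[j - 1];
      double sub = D[i - 1][j - 1] + (eq ? 0.0 : mismatch_cost);
      if (eq && D[i][j] == sub) { --i; --j; }
      else if (D[i][j] == D[i][j - 1] + del_cost) { --j; }
      else if (D[i][j] == D[i - 1][j] + ins_cost) { --i; }
      else { ++mm; --i; --j; }
    }
    return mm;
  };
  if (ties.size() > 1) {
    int best_mm = count_mismatches(ties[0]);
    std::vector<int> keep;
    keep.push_back(ties[0]);
    for (size_t t = 1; t < ties.size(); ++t) {
      int mm = count_mismatches(ties[t]);
      if (mm < best_mm) { best_mm = mm; keep.clear(); keep.push_back(ties[t]); }
      else if (mm == best_mm) keep.push_back(ties[t]);
    }
    ties = keep;
  }
  int jend = ties[(int)std::floor(::unif_rand() * ties.size()) % ties.size()];

  // traceback; ops collected in reverse
  std::string ops;
  ops.reserve(m + n);
  int i = m, j = jend;
  while (i > 0) {
    if (j == 0) { ops.push_back('I'); --i; continue; }
    // tie precedence: match, deletion, insertion, mismatch — ties at equal
    // cost resolve toward the canonical gapped representation rather than
    // scattered mismatches
    bool eq = read[i - 1] == ref[j - 1];
    double sub = D[i - 1][j - 1] + (eq ? 0.0 : mismatch_cost);
    if (eq && D[i][j] == sub) {
      ops.push_back('='); --i; --j;
    } else if (D[i][j] == D[i][j - 1] + del_cost) {
      ops.push_back('D'); --j;
    } else if (D[i][j] == D[i - 1][j] + ins_cost) {
      ops.push_back('I'); --i;
    } else {
      ops.push_back('X'); --i; --j;
    }
  }
  int ref_start = j + 1;  // first reference base consumed
  std::reverse(ops.begin(), ops.end());

  // boundary insertions -> soft clips (they only arise at reference ends)
  int lead = 0;
  while (lead < (int)ops.size() && ops[lead] == 'I') ++lead;
  int trail = 0;
  while (trail < (int)ops.size() - lead &&
         ops[ops.size() - 1 - trail] == 'I') ++trail;
  for (int k = 0; k < lead; ++k) ops[k] = 'S';
  for (int k = 0; k < trail; ++k) ops[ops.size() - 1 - k] = 'S';
  if (lead > 0) ref_start = 1;

  int n_match = 0, n_mismatch = 0, n_ins = 0, n_del = 0, n_clip = 0;
  for (size_t k = 0; k < ops.size(); ++k) {
    switch (ops[k]) {
    case '=': ++n_match; break;
    case 'X': ++n_mismatch; break;
    case 'I': ++n_ins; break;
    case 'D': ++n_del; break;
    case 'S': ++n_clip; break;
    }
  }

  // run-length CIGAR with SAM M for both = and X
  std::string cigar;
  size_t k = 0;
  while (k < ops.size()) {
    char op = ops[k];
    char samop = (op == '=' || op == 'X') ? 'M' : op;
    size_t r = k;
    while (r < ops.size() &&
           ((ops[r] == '=' || ops[r] == 'X') ? 'M' : ops[r]) == samop) ++r;
    cigar += std::to_string(r - k);
    cigar.push_back(samop);
    k = r;
  }

  return List::create(
    _["cost"] = best, _["ref_start"] = ref_start, _["cigar"] = cigar,
    _["n_match"] = n_match, _["n_mismatch"] = n_mismatch,
    _["n_ins"] = n_ins, _["n_del"] = n_del, _["n_clip"] = n_clip,
    _["n_end_ties"] = (int)ties.size());
}
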
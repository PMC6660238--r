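#include <Rcpp.h>
using namespace Rcpp;

// Batch tetrad simulator.
//
// Loci are grouped by chromosome arm; within an arm they are ordered by
// increasing genetic distance from the centromere.  Crossovers in each
// centromere-anchored interval of length dd Morgans are Poisson with mean
// 2*dd (bivalent rate), each involving one uniformly chosen chromatid of
// each parental homolog with no chromatid interference.  Crossovers form
// on intact parental molecules, so following a centromere-attached product
// outward it switches parental origin at a crossover with probability 1/2
// regardless of earlier exchanges; equivalently, each crossover swaps the
// distal origin between one product currently reading homolog-1 sequence
// and one currently reading homolog-2 sequence, both uniformly chosen.
// (This is what makes a single crossover always give second-division
// segregation and yields Haldane's mapping function between linked loci.)
// Meiosis I segregates by centromere, meiosis II separates sisters, the
// post-meiotic mitosis duplicates each product, and spores package the
// mitotic copies of the two meiosis-II products that share a meiosis-I
// pole.  Both arms of one chromosome share the centromere, hence the same
// chromatid identities and the same meiosis-I pole.
//
// Returns an integer array dim (n, L, 4) of parental origins (1 or 2):
// slots 1,2 are the two haplotypes carried by spore pair one (spores 1-2,
// mitotic duplicates), slots 3,4 those of spore pair two (spores 3-4).
//
// [[Rcpp::export]]
IntegerVector sim_tetrads_cpp(int n,
                              IntegerVector arm_of_locus,
                              IntegerVector chrom_of_arm,
                              NumericVector dd,
                              int n_chrom) {
  const int L = arm_of_locus.size();
  const int n_arm = chrom_of_arm.size();
  IntegerVector out(static_cast<R_xlen_t>(n) * L * 4);
  out.attr("dim") = IntegerVector::create(n, L, 4);

  // locus indices per arm, preserving input (centromere-outward) order
  std::vector< std::vector<int> > arm_loci(n_arm);
  for (int l = 0; l < L; ++l) arm_loci[arm_of_locus[l] - 1].push_back(l);

  std::vector<int> s(4);
  for (int i = 0; i < n; ++i) {
    // per-chromosome meiosis-I pole of homolog 1: 0 -> pair one, 1 -> pair two
    std::vector<int> flip(n_chrom);
    for (int c = 0; c < n_chrom; ++c) flip[c] = (unif_rand() < 0.5) ? 0 : 1;

    for (int a = 0; a < n_arm; ++a) {
      const std::vector<int>& loci = arm_loci[a];
      if (loci.empty()) continue;
      const int fl = flip[chrom_of_arm[a] - 1];
      // chromatids 0,1 = sisters of homolog 1; 2,3 = sisters of homolog 2
      s[0] = 1; s[1] = 1; s[2] = 2; s[3] = 2;
      for (size_t k = 0; k < loci.size(); ++k) {
        const int l = loci[k];
        const int nco = static_cast<int>(R::rpois(2.0 * dd[l]));
        for (int x = 0; x < nco; ++x) {
          // uniformly chosen origin-1 reader and origin-2 reader swap
          int pick1 = (unif_rand() < 0.5) ? 0 : 1;
          int pick2 = (unif_rand() < 0.5) ? 0 : 1;
          int ci = -1, cj = -1;
          for (int c = 0; c < 4; ++c) {
            if (s[c] == 1 && pick1-- == 0) ci = c;
            if (s[c] == 2 && pick2-- == 0) cj = c;
          }
          s[ci] = 2; s[cj] = 1;
        }
        // homolog-1 sisters feed the pair chosen by `fl`
        const R_xlen_t base = i + static_cast<R_xlen_t>(l) * n;
        const R_xlen_t slot = static_cast<R_xlen_t>(n) * L;
        if (fl == 0) {
          out[base]            = s[0];
          out[base + slot]     = s[1];
          out[base + 2 * slot] = s[2];
          out[base + 3 * slot] = s[3];
        } else {
          out[base]            = s[2];
          out[base + slot]     = s[3];
          out[base + 2 * slot] = s[0];
          out[base + 3 * slot] = s[1];
        }
      }
    }
  }
  return out;
}
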
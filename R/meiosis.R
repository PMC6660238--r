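#' Second-division segregation probability under Poisson crossovers
#'
#' With crossovers Poisson at bivalent rate `2d` per interval of `d`
#' Morgans, no crossover or chromatid interference, the probability that a
#' locus at distance `d` from its centromere segregates at the second
#' meiotic division is `s(d) = (2/3) (1 - exp(-3 d))`: conditioning on `k`
#' crossovers, the per-count recursion `s_k = (2/3) (1 - (-1/2)^k)` mixes
#' over the Poisson to the closed form.  SDS is capped at 2/3 (random
#' spindle attachment limit).
#'
#' @param d genetic distance in Morgans, `>= 0` (vectorised).
#' @return SDS probability in `[0, 2/3)`.
#' @seealso [distance_for_fds()] for the inverse.
#' @export
sds_probability <- function(d) {
  if (any(d < 0)) stop("genetic distance d must be >= 0")
  (2 / 3) * (1 - exp(-3 * d))
}

#' Map distance producing a given first-division segregation frequency
#'
#' Inverts [sds_probability()]: returns `d` with `1 - s(d) = f`.  Because
#' SDS saturates at 2/3, FDS frequencies at or below 1/3 are unattainable.
#' Used to calibrate the Spok2 locus to the observed ~40% spore killing.
#'
#' @param f FDS probability, `1/3 < f <= 1` (vectorised).
#' @return distance in Morgans.
#' @export
distance_for_fds <- function(f) {
  if (any(f > 1)) stop("FDS frequency f must be <= 1")
  if (any(f <= 1 / 3))
    stop("FDS frequency f must exceed 1/3 (SDS cannot exceed 2/3 ",
         "under the crossover model)")
  -log(1 - 1.5 * (1 - f)) / 3
}

# Batch meiosis: origins array (n, L, 4).  Slots 1,2 = the two haplotypes of
# spore pair one (spores 1-2), slots 3,4 = spore pair two (spores 3-4).
sim_meioses <- function(map, n) {
  stopifnot(inherits(map, "genetic_map"), n >= 1)
  o <- sim_tetrads_cpp(as.integer(n), as.integer(map$.arm),
                       attr(map, "chrom_of_arm"), map$.dd,
                       max(attr(map, "chrom_of_arm")))
  dimnames(o) <- list(NULL, map$name, NULL)
  o
}

#' Simulate one Podospora meiosis (an ascus, before killing)
#'
#' Builds four chromatids per chromosome, lays down crossovers per
#' centromere-anchored interval (Poisson, mean twice the interval length in
#' Morgans, no chromatid interference), segregates homologous centromeres at
#' meiosis I and sisters at meiosis II, duplicates each product mitotically,
#' and packages spores from the mitotic copies of the two meiosis-II
#' products sharing a meiosis-I pole (non-sister packaging).  Spores 1-2
#' are mitotic duplicates, as are spores 3-4.
#'
#' @param p1,p2 parental [strain_genotype()]s on the same map.
#' @param map a [genetic_map()].
#' @param seed optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return an object of class `ascus`: parental-origin matrix (locus x 4
#'   haplotype slots), the per-locus FDS/SDS call (`fds_by_locus`, for loci
#'   heteroallelic between the parents), and the parents.
#' @export
simulate_tetrad <- function(p1, p2, map, seed = NULL) {
  stopifnot(inherits(p1, "strain_genotype"), inherits(p2, "strain_genotype"))
  if (!is.null(seed)) set.seed(seed)
  unknown <- setdiff(c(names(p1$alleles), names(p2$alleles)), map$name)
  if (length(unknown))
    stop("parents and map disagree: loci not on map: ",
         paste(unknown, collapse = ", "))
  o <- sim_meioses(map, 1L)
  origins <- matrix(o[1, , ], nrow = nrow(map), ncol = 4,
                    dimnames = list(map$name, NULL))
  het <- heteroallelic_loci(p1, p2, map)
  sds <- origins[, 1] != origins[, 2]
  fds_by_locus <- setNames(ifelse(sds[het], "SDS", "FDS"), het)
  structure(list(origins = origins, map = map, parents = list(p1, p2),
                 fds_by_locus = fds_by_locus),
            class = "ascus")
}

#' @export
print.ascus <- function(x, ...) {
  cat("<ascus> 4 dikaryotic spores;",
      sprintf("%d locus/loci heteroallelic (%s)\n", length(x$fds_by_locus),
              paste(sprintf("%s:%s", names(x$fds_by_locus), x$fds_by_locus),
                    collapse = ", ")))
  invisible(x)
}

#' Nuclei of an ascus
#'
#' Expands the compact origin representation into the eight post-mitotic
#' nuclei: spore `s` holds nuclei `2s-1` and `2s`; each nucleus is the
#' per-locus list of alleles inherited from its parent of origin.
#'
#' @param ascus an `ascus` from [simulate_tetrad()].
#' @return list of 8 nuclei; each nucleus is
#'   `list(spore, origin = per-locus parent index, alleles)`.
#' @export
ascus_nuclei <- function(ascus) {
  slots <- c(1, 2, 1, 2, 3, 4, 3, 4)  # haplotype slot backing each nucleus
  lapply(seq_len(8), function(i) {
    org <- ascus$origins[, slots[i]]
    alleles <- lapply(seq_along(org), function(l) {
      alleles_at(ascus$parents[[org[l]]], rownames(ascus$origins)[l])
    })
    names(alleles) <- rownames(ascus$origins)
    list(spore = (i + 1) %/% 2, origin = org, alleles = alleles)
  })
}

# genotype carried by haplotype slot `slot` of an ascus origins row-set
nucleus_genotype <- function(origins, map, p1, p2, slot, name = "nucleus") {
  parents <- list(p1, p2)
  org <- origins[, slot]
  alleles <- list()
  tags <- character(0)
  for (l in map$name) {
    a <- alleles_at(parents[[org[l]]], l)
    if (length(a)) alleles[[l]] <- a
    pt <- parents[[org[l]]]$tags
    tags[l] <- if (!is.null(pt) && !is.na(pt[l])) pt[l]
               else c("p1", "p2")[org[l]]
  }
  strain_genotype(name, alleles, tags = tags)
}
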
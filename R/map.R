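#' Genetic map of loci anchored at centromeres
#'
#' A map is a data frame of loci, each placed on a chromosome arm at a
#' genetic distance `d` (Morgans) from the centromere.  Within an arm loci
#' are strictly ordered by `d`.  A Spok block (the large mobile region
#' carrying Spok3 and/or Spok4) occupies exactly one locus and never
#' recombines internally: its allele list is its gene content.
#'
#' @param loci data frame with columns `name`, `chromosome`, `arm`
#'   (`"L"`/`"R"`) and `d` (Morgans, `>= 0`).
#' @return a `genetic_map`: the sorted data frame with arm/chromosome index
#'   columns used by the simulator.
#' @export
genetic_map <- function(loci) {
  stopifnot(is.data.frame(loci),
            all(c("name", "chromosome", "arm", "d") %in% names(loci)))
  loci$name <- as.character(loci$name)
  loci$chromosome <- as.integer(loci$chromosome)
  loci$arm <- as.character(loci$arm)
  loci$d <- as.numeric(loci$d)
  if (any(is.na(loci$chromosome)) || any(loci$chromosome < 1L))
    stop("chromosome must be a positive integer")
  if (!all(loci$arm %in% c("L", "R"))) stop("arm must be 'L' or 'R'")
  if (any(loci$d < 0)) stop("genetic distances d must be >= 0")
  if (anyDuplicated(loci$name)) stop("locus names must be unique")
  loci <- loci[order(loci$chromosome, loci$arm, loci$d), , drop = FALSE]
  rownames(loci) <- NULL
  arm_key <- paste0(loci$chromosome, loci$arm)
  dup <- stats::ave(loci$d, arm_key, FUN = function(x) duplicated(x))
  if (any(dup > 0))
    stop("loci within one arm must be strictly ordered by d (ties found)")
  arms <- unique(arm_key)
  loci$.arm <- match(arm_key, arms)
  # interval length from the previous locus (or centromere) on the same arm
  loci$.dd <- loci$d -
    stats::ave(loci$d, arm_key, FUN = function(x) c(0, head(x, -1)))
  attr(loci, "chrom_of_arm") <-
    as.integer(sub("[LR]$", "", arms))
  class(loci) <- c("genetic_map", "data.frame")
  loci
}

#' @rdname genetic_map
#' @param name,chromosome,arm,d scalar locus fields.
#' @export
locus <- function(name, chromosome, arm, d) {
  data.frame(name = name, chromosome = chromosome, arm = arm, d = d,
             stringsAsFactors = FALSE)
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> %d loci on %d chromosome arm(s)\n",
              nrow(x), length(attr(x, "chrom_of_arm"))))
  print(as.data.frame(x)[, c("name", "chromosome", "arm", "d")])
  invisible(x)
}

#' Default P. anserina map used by the strain registry
#'
#' Holds the Spok2 locus and the four observed Spok-block insertion sites,
#' the centromere-linked PaPKS1 knock-in locus, the Spok1 locus of
#' P. comata, and the mating-type locus (carried but ignored by the drive
#' machinery).  The Spok2 distance is calibrated so that its first-division
#' segregation frequency matches the observed 40.6% spore killing of the
#' s x delta-Spok2 cross; the block distances are not published and are
#' assumed (FDS 0.90 at 3L and 4R, 0.75 at the 5L block site, 0.50 at 5R).
#'
#' @param markers if `TRUE`, add neutral biallelic markers every
#'   `marker_spacing` Morgans along each arm (used for introgression
#'   tracking).
#' @param marker_spacing marker grid spacing in Morgans.
#' @param arm_length arm length in Morgans for the marker grid.
#' @return a [genetic_map()].
#' @export
default_genetic_map <- function(markers = FALSE, marker_spacing = 0.1,
                                arm_length = 1) {
  loci <- rbind(
    locus("mat",       1, "R", 0.30),
    locus("papks1",    2, "L", 0.00),
    locus("block_3L",  3, "L", distance_for_fds(0.90)),
    locus("spok1",     4, "L", 0.15),
    locus("block_4R",  4, "R", distance_for_fds(0.90)),
    locus("spok2",     5, "L", distance_for_fds(0.406)),
    locus("block_5L",  5, "L", distance_for_fds(0.75)),
    locus("block_5R",  5, "R", distance_for_fds(0.50)),
    locus("spokpsi1",  5, "R", 0.90))
  if (markers)
    loci <- rbind(loci, marker_grid(chromosomes = 1:7,
                                    spacing = marker_spacing,
                                    arm_length = arm_length,
                                    avoid = loci))
  genetic_map(loci)
}

#' Neutral marker grid
#'
#' @param chromosomes integer vector of chromosomes to cover.
#' @param spacing grid spacing in Morgans.
#' @param arm_length arm length in Morgans.
#' @param avoid data frame of loci whose positions must not be duplicated.
#' @return data frame of marker loci named `mk<chrom><arm>_<d>`.
#' @export
marker_grid <- function(chromosomes = 1:7, spacing = 0.1, arm_length = 1,
                        avoid = NULL) {
  if (arm_length <= 0) stop("arm_length must be positive")
  if (spacing <= 0) stop("marker spacing must be positive")
  pos <- seq(spacing, arm_length, by = spacing)
  out <- do.call(rbind, lapply(chromosomes, function(ch) {
    do.call(rbind, lapply(c("L", "R"), function(arm) {
      locus(sprintf("mk%d%s_%g", ch, arm, pos), ch, arm, pos)
    }))
  }))
  if (!is.null(avoid)) {
    clash <- paste(out$chromosome, out$arm, out$d) %in%
      paste(avoid$chromosome, avoid$arm, avoid$d)
    out <- out[!clash, , drop = FALSE]
  }
  out
}
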
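#' Haploid strain genotype
#'
#' A genotype assigns to each named locus a list of Spok alleles (an empty
#' list is the null allele; a block locus may carry several genes, e.g.
#' Spok3+Spok4, or two Spok3 copies as in strain T_G).  Loci absent from
#' `alleles` are null.  `tags` carries optional parent-of-origin labels per
#' locus, used for introgression tracking.
#'
#' @param name strain name.
#' @param alleles named list: locus name -> list of [spok_allele()].
#' @param mating_type `"+"`, `"-"` or `NA`; stored but ignored by the
#'   segregation machinery (crosses are assumed compatible).
#' @param tags optional named character vector: locus name -> origin tag.
#' @return an object of class `strain_genotype`.
#' @export
strain_genotype <- function(name, alleles = list(), mating_type = NA_character_,
                            tags = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(alleles)) {
    stopifnot(!is.null(names(alleles)), all(nzchar(names(alleles))))
    if (anyDuplicated(names(alleles)))
      stop("haploid genotype: exactly one allele list per locus")
    for (l in names(alleles)) {
      if (inherits(alleles[[l]], "spok_allele"))
        alleles[[l]] <- list(alleles[[l]])
      ok <- vapply(alleles[[l]], inherits, logical(1), "spok_allele")
      if (!all(ok)) stop("alleles at locus '", l, "' must be spok_allele objects")
    }
  }
  structure(list(name = name, alleles = alleles,
                 mating_type = mating_type, tags = tags),
            class = "strain_genotype")
}

#' @export
print.strain_genotype <- function(x, ...) {
  cat(sprintf("<strain_genotype> %s\n", x$name))
  if (!length(x$alleles)) {
    cat("  (no Spok alleles)\n")
  } else {
    for (l in names(x$alleles)) {
      labs <- vapply(x$alleles[[l]], `[[`, character(1), "label")
      cat(sprintf("  %-10s %s\n", l,
                  if (length(labs)) paste(labs, collapse = " + ") else "-"))
    }
  }
  invisible(x)
}

alleles_at <- function(genotype, locus_name) {
  a <- genotype$alleles[[locus_name]]
  if (is.null(a)) list() else a
}

# loci at which the two parents carry different allele complements
heteroallelic_loci <- function(p1, p2, map) {
  key <- function(g, l) {
    a <- alleles_at(g, l)
    paste(sort(vapply(a, `[[`, character(1), "label")), collapse = "|")
  }
  map$name[vapply(map$name, function(l) key(p1, l) != key(p2, l), logical(1))]
}

# loci carrying any Spok allele in either parent (drive loci)
drive_loci <- function(p1, p2, map) {
  map$name[vapply(map$name, function(l) {
    length(alleles_at(p1, l)) > 0 || length(alleles_at(p2, l)) > 0
  }, logical(1))]
}

#' Default strain registry
#'
#' Genotypes transcribed from the sequenced natural isolates (Spok content
#' and Spok-block arm per strain) plus the laboratory strains used in the
#' knock-in crosses.  The P. pauciseta strain CBS237.71 is entered with
#' block content Spok3 only, following the strain table; the alternate
#' reading of the text (block carries Spok3 and Spok4) is available as
#' `"CBS237.71-alt"` -- the discrepancy is deliberately left to the user.
#'
#' @return named list of [strain_genotype()] objects.
#' @export
default_strain_registry <- function() {
  s2 <- function() spok_allele("Spok2")
  s3 <- function() spok_allele("Spok3")
  s4 <- function() spok_allele("Spok4")
  psi <- function() spok_allele("SpokPsi1")
  g <- list(
    strain_genotype("S",     list(spok2 = list(s2())), "+"),
    strain_genotype("s",     list(spok2 = list(s2())), "+"),
    strain_genotype("Wa63",  list(spok2 = list(s2())), "+"),
    strain_genotype("Us5",   list(spok2 = list(s2())), "+"),
    strain_genotype("Wa46",  list(spokpsi1 = list(psi())), "+"),
    strain_genotype("Wa47",  list(), "+"),
    strain_genotype("Wa21",  list(spok2 = list(s2()),
                                  block_5R = list(s3())), "-"),
    strain_genotype("Wa28",  list(spok2 = list(s2()),
                                  block_5R = list(s3())), "-"),
    strain_genotype("Wa53",  list(spok2 = list(s2()),
                                  block_3L = list(s3(), s4())), "-"),
    strain_genotype("Wa87",  list(spok2 = list(s2()),
                                  block_3L = list(s3(), s4()),
                                  spokpsi1 = list(psi())), "+"),
    strain_genotype("Wa58",  list(spok2 = list(s2()),
                                  block_5L = list(s3(), s4())), "-"),
    strain_genotype("Y",     list(block_3L = list(s3(), s4())), "+"),
    strain_genotype("Wa100", list(spok2 = list(s2()),
                                  block_5L = list(s4()),
                                  spokpsi1 = list(psi())), "+"),
    strain_genotype("T_G",   list(block_3L = list(s3(), s3(), s4())), "+"),
    strain_genotype("T_D",   list(spok1 = list(spok_allele("Spok1"))), "+"),
    strain_genotype("CBS237.71",
                    list(spok2 = list(s2()), block_4R = list(s3())), "-"),
    strain_genotype("CBS237.71-alt",
                    list(spok2 = list(s2()), block_4R = list(s3(), s4())), "-"),
    strain_genotype("A",     list(spok2 = list(spok2_strainA())), "+"),
    # laboratory strains of the knock-in experiments
    strain_genotype("s_dSpok2", list(), "+"),
    strain_genotype("Spok3_PaPKS1",  list(papks1 = list(s3())), "+"),
    strain_genotype("Spok4_PaPKS1",  list(papks1 = list(s4())), "+"),
    strain_genotype("Spok3_PaPKS1d", list(papks1 = list(s3())), "-"),
    strain_genotype("Spok3_PaPKS1d_dSpok2", list(papks1 = list(s3())), "-"),
    strain_genotype("Spok4_PaPKS1_dSpok2",  list(papks1 = list(s4())), "-"),
    strain_genotype("Spok3_K240A_PaPKS1",
                    list(papks1 = list(spok3_K240A())), "+"))
  setNames(g, vapply(g, `[[`, character(1), "name"))
}

#' Look up a strain in a registry
#'
#' @param strain_name strain name.
#' @param registry named list of genotypes, by default
#'   [default_strain_registry()].
#' @return a [strain_genotype()].
#' @export
genotype_of <- function(strain_name, registry = default_strain_registry()) {
  g <- registry[[strain_name]]
  if (is.null(g))
    stop("unknown strain '", strain_name, "' (not in registry)")
  g
}

#' Psk spore-killer type of a genotype
#'
#' The Psk label is an emergent property of the kill-capable Spok content
#' and of the chromosome arm carrying the Spok block: three-Spok strains
#' are Psk-1 (block on 3L) or Psk-7 (5L); two-Spok strains are Psk-2
#' (Spok2+Spok3, 5R), Psk-5 (Spok3+Spok4, no Spok2) or Psk-8 (Spok2+Spok4,
#' 5L); Spok2 alone is Psk-S; no functional Spok is naive.  The P. pauciseta
#' and P. comata killers carry their own labels (Psk-P1, Psk-C1).
#' Unmapped combinations return `"unclassified:<description>"`.
#'
#' @param g a [strain_genotype()].
#' @param map the [genetic_map()] that places block loci on arms.
#' @return character Psk label.
#' @export
psk_type_of <- function(g, map = default_genetic_map()) {
  stopifnot(inherits(g, "strain_genotype"))
  all_alleles <- unlist(g$alleles, recursive = FALSE)
  killers <- sort(unique(vapply(
    Filter(function(a) a$kills, all_alleles), `[[`, character(1), "homolog")))
  nm <- names(g$alleles)
  if (is.null(nm)) nm <- character(0)
  block_loci <- nm[startsWith(nm, "block_") & lengths(g$alleles) > 0]
  arm_of <- function(l) {
    i <- match(l, map$name)
    if (is.na(i)) sub("^block_", "", l) else paste0(map$chromosome[i], map$arm[i])
  }
  arms <- vapply(block_loci, arm_of, character(1))
  ks <- paste(killers, collapse = "+")
  lab <- if (length(killers) == 0) "naive"
  else if (ks == "Spok1") "Psk-C1"
  else if (ks == "Spok2") "Psk-S"
  else if (ks == "Spok2+Spok3+Spok4" && identical(unname(arms), "3L")) "Psk-1"
  else if (ks == "Spok2+Spok3+Spok4" && identical(unname(arms), "5L")) "Psk-7"
  else if (ks == "Spok2+Spok3+Spok4" && identical(unname(arms), "4R")) "Psk-P1"
  else if (ks == "Spok2+Spok3" && identical(unname(arms), "5R")) "Psk-2"
  else if (ks == "Spok2+Spok3" && identical(unname(arms), "4R")) "Psk-P1"
  else if (ks == "Spok3+Spok4") "Psk-5"
  else if (ks == "Spok2+Spok4" && identical(unname(arms), "5L")) "Psk-8"
  else sprintf("unclassified:{%s}@%s", ks, paste(arms, collapse = ","))
  lab
}

## ---- registry I/O (YAML) ----------------------------------------------

allele_to_list <- function(a) {
  list(homolog = a$homolog, kills = a$kills,
       resists = as.list(a$resists), label = a$label)
}

allele_from_list <- function(x) {
  spok_allele(x$homolog, kills = x$kills,
              resists = unlist(x$resists), label = x$label)
}

#' Read and write a strain registry configuration
#'
#' The configuration is a YAML document holding the genetic map (loci with
#' chromosome, arm and distance in Morgans), the strains (per-locus allele
#' lists) and optionally the resistance/penetrance model.  Generators write
#' the same format the analysis reads, so file round-trips are exact.
#'
#' @param path file path.
#' @param registry named list of [strain_genotype()].
#' @param map a [genetic_map()].
#' @param model optional [resistance_model()].
#' @return `read_registry` returns `list(map, registry, model)`;
#'   `write_registry` returns `path` invisibly.
#' @export
write_registry <- function(path, registry, map, model = NULL) {
  doc <- list(
    map = lapply(seq_len(nrow(map)), function(i) {
      list(name = map$name[i], chromosome = map$chromosome[i],
           arm = map$arm[i], d = map$d[i])
    }),
    strains = lapply(unname(registry), function(g) {
      list(name = g$name, mating_type = g$mating_type,
           loci = lapply(g$alleles, function(al) lapply(al, allele_to_list)))
    }))
  if (!is.null(model)) {
    R <- model$resistance
    pairs <- which(R, arr.ind = TRUE)
    doc$model <- list(
      kill_capable = as.list(model$kill_capable),
      resistance_pairs = lapply(seq_len(nrow(pairs)), function(i) {
        list(killer = rownames(R)[pairs[i, 1]],
             carried = colnames(R)[pairs[i, 2]])
      }),
      penetrance = as.list(model$penetrance))
  }
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  doc <- yaml::read_yaml(path)
  map <- genetic_map(do.call(rbind, lapply(doc$map, function(l) {
    locus(l$name, l$chromosome, l$arm, l$d)
  })))
  registry <- lapply(doc$strains, function(s) {
    alleles <- lapply(s$loci, function(al) lapply(al, allele_from_list))
    strain_genotype(s$name, alleles,
                    mating_type = if (is.null(s$mating_type)) NA_character_
                                  else s$mating_type)
  })
  registry <- setNames(registry,
                       vapply(registry, `[[`, character(1), "name"))
  model <- NULL
  if (!is.null(doc$model)) {
    kc <- unlist(doc$model$kill_capable)
    h <- names(kc)
    R <- matrix(FALSE, length(h), length(h),
                dimnames = list(killer = h, carried = h))
    for (p in doc$model$resistance_pairs) R[p$killer, p$carried] <- TRUE
    model <- resistance_model(kc, R, unlist(doc$model$penetrance))
  }
  list(map = map, registry = registry, model = model)
}
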
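#' Construct a Spok allele
#'
#' A Spok allele couples a killing competence with a resistance profile.
#' Wild-type `Spok1`--`Spok4` alleles kill; the pseudogene `SpokPsi1` does
#' not.  Laboratory and natural loss-of-function variants are expressed as
#' attribute overrides of the parental homolog rather than as new homologs:
#' `spok3_K240A()` (nuclease-dead, resistance retained) and
#' `spok2_strainA()` (the naturally resistant-but-non-killing allele).
#'
#' @param homolog homolog identifier, e.g. `"Spok2"`; user-defined names are
#'   allowed.
#' @param kills does the allele kill?  Defaults to `TRUE` for
#'   `Spok1`--`Spok4`, `FALSE` otherwise.
#' @param resists character vector of killer homologs this allele resists in
#'   addition to what the [resistance_model()] grants its homolog.  A killer
#'   allele must resist its own homolog (a killer never kills its carrier);
#'   this is enforced at construction.
#' @param label free-text allele label, e.g. `"Spok3-K240A"`.
#' @return an object of class `spok_allele`.
#' @export
spok_allele <- function(homolog, kills = NULL,
                        resists = NULL, label = homolog) {
  stopifnot(is.character(homolog), length(homolog) == 1L, nzchar(homolog))
  if (is.null(kills))
    kills <- homolog %in% c("Spok1", "Spok2", "Spok3", "Spok4")
  stopifnot(is.logical(kills), length(kills) == 1L, !is.na(kills))
  if (is.null(resists)) resists <- if (kills) homolog else character(0)
  resists <- unique(as.character(resists))
  if (kills && !(homolog %in% resists))
    stop("killer allele '", label, "' must resist its own homolog '",
         homolog, "' (a killer never kills its carrier)")
  structure(list(homolog = homolog, kills = kills,
                 resists = resists, label = label),
            class = "spok_allele")
}

#' @export
print.spok_allele <- function(x, ...) {
  cat(sprintf("<spok_allele> %s (%s): kills=%s, resists={%s}\n",
              x$label, x$homolog, x$kills, paste(x$resists, collapse = ",")))
  invisible(x)
}

#' @rdname spok_allele
#' @export
spok3_K240A <- function() {
  spok_allele("Spok3", kills = FALSE, resists = "Spok3", label = "Spok3-K240A")
}

#' @rdname spok_allele
#' @export
spok2_strainA <- function() {
  spok_allele("Spok2", kills = FALSE, resists = "Spok2",
              label = "Spok2-strainA")
}

#' Killer/resistance model
#'
#' The model holds, per homolog, whether it is kill-competent, the pairwise
#' resistance matrix `resistance[killer, carried]` (does a carried allele of
#' homolog `carried` protect against killer homolog `killer`?), and a
#' per-homolog penetrance `q` (per-spore probability that an unresisted
#' killer actually kills; `q < 1` generates three-spored asci).
#'
#' `default_resistance_model()` encodes the interactions established by the
#' knock-in crosses and the interspecies matings: within P. anserina the
#' homologs are functionally independent (identity-only resistance: Spok2,
#' Spok3 and Spok4 each resist only themselves), Spok1 of P. comata resists
#' all four and kills in the presence of Spok2 and Spok3, and Spok4 resists
#' Spok1.  SpokPsi1 neither kills nor resists.
#'
#' @param kill_capable named logical vector by homolog.
#' @param resistance named logical matrix, rows = killer homolog, columns =
#'   carried homolog.  Every kill-capable homolog must self-resist.
#' @param penetrance named numeric vector in `[0, 1]`; homologs absent from
#'   the vector default to 1.
#' @return an object of class `resistance_model`.
#' @export
resistance_model <- function(kill_capable, resistance, penetrance = numeric(0)) {
  stopifnot(is.logical(kill_capable), !is.null(names(kill_capable)),
            is.matrix(resistance), is.logical(resistance))
  h <- names(kill_capable)
  stopifnot(identical(rownames(resistance), h),
            identical(colnames(resistance), h))
  bad <- h[kill_capable & !diag(resistance)]
  if (length(bad))
    stop("kill-capable homolog(s) must self-resist: ",
         paste(bad, collapse = ", "))
  if (length(penetrance)) {
    stopifnot(!is.null(names(penetrance)))
    if (any(penetrance < 0 | penetrance > 1))
      stop("penetrance values must lie in [0, 1]")
  }
  structure(list(kill_capable = kill_capable, resistance = resistance,
                 penetrance = penetrance),
            class = "resistance_model")
}

#' @rdname resistance_model
#' @export
default_resistance_model <- function() {
  h <- c("Spok1", "Spok2", "Spok3", "Spok4", "SpokPsi1")
  kc <- setNames(c(TRUE, TRUE, TRUE, TRUE, FALSE), h)
  R <- matrix(FALSE, 5, 5, dimnames = list(killer = h, carried = h))
  diag(R)[1:4] <- TRUE
  # Spok1 resists every P. anserina homolog ...
  R["Spok2", "Spok1"] <- TRUE
  R["Spok3", "Spok1"] <- TRUE
  R["Spok4", "Spok1"] <- TRUE
  # ... and Spok4 resists Spok1 (mutual resistance of Psk-5 with P. comata)
  R["Spok1", "Spok4"] <- TRUE
  resistance_model(kc, R)
}

#' Query the resistance matrix
#'
#' Does a carried allele of homolog `carried` protect against killer homolog
#' `killer`?  Homologs unknown to the model default to identity-only
#' resistance (`killer == carried`).
#'
#' @param model a [resistance_model()].
#' @param killer,carried homolog identifiers.
#' @return logical.
#' @export
model_resists <- function(model, killer, carried) {
  h <- rownames(model$resistance)
  if (killer %in% h && carried %in% h)
    return(unname(model$resistance[killer, carried]))
  killer == carried
}

#' @rdname resistance_model
#' @param homolog homolog identifier.
#' @param model a `resistance_model`.
#' @export
model_penetrance <- function(model, homolog) {
  q <- model$penetrance[homolog]
  ifelse(is.na(q), 1, unname(q))
}

#' @rdname resistance_model
#' @export
model_kill_capable <- function(model, homolog) {
  kc <- model$kill_capable[homolog]
  ifelse(is.na(kc), TRUE, unname(kc))
}

#' Set per-homolog penetrance on a model
#'
#' @param model a [resistance_model()].
#' @param ... named penetrance values, e.g. `Spok2 = 0.72`.
#' @return the modified model.
#' @export
set_penetrance <- function(model, ...) {
  q <- unlist(list(...))
  if (any(q < 0 | q > 1)) stop("penetrance values must lie in [0, 1]")
  model$penetrance[names(q)] <- q
  model
}

#' @export
print.resistance_model <- function(x, ...) {
  cat("<resistance_model>\n  kill-capable:",
      paste(names(x$kill_capable)[x$kill_capable], collapse = ", "), "\n")
  cat("  resistance matrix (killer x carried):\n")
  print(x$resistance)
  if (length(x$penetrance)) {
    cat("  penetrance overrides:",
        paste(sprintf("%s=%g", names(x$penetrance), x$penetrance),
              collapse = ", "), "\n")
  } else cat("  penetrance: 1 for all homologs\n")
  invisible(x)
}

# does any allele in `alleles` protect against `killer`?
alleles_resist <- function(alleles, killer, model) {
  for (a in alleles) {
    if (killer %in% a$resists) return(TRUE)
    if (model_resists(model, killer, a$homolog)) return(TRUE)
  }
  FALSE
}

#' Is a spore resistant to a killer homolog?
#'
#' A spore is resistant iff some allele it carries (in either nucleus)
#' protects against the killer, through the model's resistance matrix or
#' through the allele's own `resists` override.
#'
#' @param carried list of [spok_allele()] objects carried by the spore.
#' @param killer_homolog killer homolog identifier.
#' @param model a [resistance_model()].
#' @return logical.
#' @export
is_resistant <- function(carried, killer_homolog,
                         model = default_resistance_model()) {
  alleles_resist(carried, killer_homolog, model)
}
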
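#' Assemble the emergent Psk killing hierarchy
#'
#' Classifies every pair of genotypes with [classify_interaction()] and
#' organises the verdicts as a graph: directed dominance edges, undirected
#' mutual-killing / mutual-resistance / same-type edges, and hierarchy
#' levels computed as longest-path strata of the dominance DAG (level 1 =
#' top killers; larger numbers are increasingly subordinate, naive strains
#' at the bottom).
#'
#' @param genotypes named list of [strain_genotype()]s (>= 2); names (or
#'   Psk labels when unnamed) become graph nodes.
#' @param map,model,n_asci,seed,threshold passed to
#'   [classify_interaction()].
#' @return a `hierarchy_graph`: `nodes`, `dominance` (data frame
#'   `from`/`to`), `mutual_killing`, `mutual_resistance`, `same_type`
#'   (data frames `a`/`b`), `levels` (named integer vector) and the raw
#'   `calls`.
#' @export
build_hierarchy <- function(genotypes, map = default_genetic_map(),
                            model = default_resistance_model(),
                            n_asci = 1000, seed = NULL, threshold = 0.05) {
  stopifnot(length(genotypes) >= 1)
  if (!is.null(seed)) set.seed(seed)
  labels <- names(genotypes)
  if (is.null(labels))
    labels <- vapply(genotypes, psk_type_of, character(1), map = map)
  if (anyDuplicated(labels)) stop("node labels must be unique")
  n <- length(genotypes)
  edge <- function() data.frame(a = character(0), b = character(0))
  dominance <- data.frame(from = character(0), to = character(0))
  mk <- edge(); mr <- edge(); st <- edge()
  calls <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      cl <- classify_interaction(genotypes[[i]], genotypes[[j]], map, model,
                                 n_asci = n_asci, threshold = threshold)
      calls[[paste(labels[i], labels[j], sep = " x ")]] <- cl
      v <- cl$verdict
      if (v == "dominance") {
        dom <- if (cl$dominant == genotypes[[i]]$name) i else j
        sub <- if (dom == i) j else i
        dominance <- rbind(dominance,
                           data.frame(from = labels[dom], to = labels[sub]))
      } else if (v == "mutual_killing") {
        mk <- rbind(mk, data.frame(a = labels[i], b = labels[j]))
      } else if (v == "mutual_resistance") {
        mr <- rbind(mr, data.frame(a = labels[i], b = labels[j]))
      } else if (v == "same_type") {
        st <- rbind(st, data.frame(a = labels[i], b = labels[j]))
      } else {
        stop("unstable interaction call for ", labels[i], " x ", labels[j],
             "; increase n_asci")
      }
    }
  }
  levels <- dominance_levels(labels, dominance)
  structure(list(nodes = labels, dominance = dominance, mutual_killing = mk,
                 mutual_resistance = mr, same_type = st, levels = levels,
                 calls = calls),
            class = "hierarchy_graph")
}

# longest-path strata of the dominance DAG; level(v) = 1 + longest chain of
# dominators above v.  Errors on a cycle (a model-integrity violation).
dominance_levels <- function(nodes, dominance) {
  lev <- setNames(rep(NA_integer_, length(nodes)), nodes)
  indeg_from <- function(v) dominance$from[dominance$to == v]
  visiting <- character(0)
  assign_level <- function(v) {
    if (!is.na(lev[[v]])) return(lev[[v]])
    if (v %in% visiting) stop("dominance cycle detected at '", v, "'")
    visiting <<- c(visiting, v)
    ups <- indeg_from(v)
    l <- if (!length(ups)) 1L
         else 1L + max(vapply(ups, assign_level, integer(1)))
    visiting <<- setdiff(visiting, v)
    lev[[v]] <<- l
    l
  }
  for (v in nodes) assign_level(v)
  lev
}

#' @export
print.hierarchy_graph <- function(x, ...) {
  cat(sprintf("<hierarchy_graph> %d node(s)\n", length(x$nodes)))
  for (l in sort(unique(x$levels)))
    cat(sprintf("  level %d: %s\n", l,
                paste(names(x$levels)[x$levels == l], collapse = ", ")))
  if (nrow(x$dominance))
    cat("  dominance:", paste(sprintf("%s > %s", x$dominance$from,
                                      x$dominance$to), collapse = "; "), "\n")
  if (nrow(x$mutual_killing))
    cat("  mutual killing:", paste(sprintf("%s ~ %s", x$mutual_killing$a,
                                           x$mutual_killing$b),
                                   collapse = "; "), "\n")
  if (nrow(x$mutual_resistance))
    cat("  mutual resistance:", paste(sprintf("%s = %s",
                                              x$mutual_resistance$a,
                                              x$mutual_resistance$b),
                                      collapse = "; "), "\n")
  invisible(x)
}

#' Export a hierarchy graph in DOT format
#'
#' @param x a `hierarchy_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
hierarchy_to_dot <- function(x, path) {
  lines <- c("digraph psk_hierarchy {",
             sprintf('  "%s";', x$nodes),
             sprintf('  "%s" -> "%s";', x$dominance$from, x$dominance$to),
             sprintf('  "%s" -> "%s" [dir=both, color=red, label="MK"];',
                     x$mutual_killing$a, x$mutual_killing$b),
             sprintf('  "%s" -> "%s" [dir=none, style=dashed, label="MR"];',
                     x$mutual_resistance$a, x$mutual_resistance$b),
             "}")
  writeLines(lines, path)
  invisible(path)
}
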
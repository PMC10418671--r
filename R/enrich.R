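# Pathway over-representation analysis: hypergeometric test of a selected
# metabolite set against a pathway catalog, over the universe of annotated
# metabolites that survived preprocessing.

#' Construct a pathway catalog
#'
#' @param pathways named list: pathway id -> character vector of metabolite
#'   names
#' @param universe character vector of all annotated metabolite names (the
#'   background); pathway members outside it are trimmed, empty pathways
#'   dropped with a warning
#' @return a `pathway_catalog`
#' @export
pathway_catalog <- function(pathways, universe) {
  universe <- unique(norm_name(universe))
  paths <- lapply(pathways, function(s) intersect(unique(norm_name(s)), universe))
  empty <- lengths(paths) == 0L
  if (any(empty)) {
    warnf("dropping %d empty pathway(s): %s", sum(empty),
          paste(names(paths)[empty], collapse = ", "))
    paths <- paths[!empty]
  }
  structure(list(pathways = paths, universe = universe),
            class = "pathway_catalog")
}

# Case-insensitive, whitespace-normalized metabolite name key.
norm_name <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Match metabolite names against a catalog universe
#'
#' Case-insensitive exact matching after whitespace normalization; no
#' fuzzy matching. Duplicates are removed.
#'
#' @param selected character vector of metabolite names
#' @param catalog a `pathway_catalog`
#' @return list with `matched` (normalized names in the universe),
#'   `unmatched` (original spellings not found) and `n_duplicates`
#' @export
match_names <- function(selected, catalog) {
  key <- norm_name(selected)
  dup <- duplicated(key)
  key_u <- key[!dup]
  orig_u <- selected[!dup]
  hit <- key_u %in% catalog$universe
  list(matched = key_u[hit], unmatched = orig_u[!hit],
       n_duplicates = sum(dup))
}

#' Hypergeometric over-representation analysis
#'
#' Per pathway, `p = P(X >= k)` for `X ~ hypergeometric(N, K, n)` with `N`
#' the universe size, `K` the pathway size, `n` the number of selected
#' metabolites and `k` the overlap, computed with the stable survival
#' function. Results are sorted by p ascending with Benjamini-Hochberg
#' q-values attached.
#'
#' @param selected character vector of selected metabolite names; names
#'   outside the universe are reported and dropped
#' @param catalog a `pathway_catalog`
#' @return data.frame: pathway_id, k, K, n, N, p, q; attribute `unmatched`
#' @export
enrich <- function(selected, catalog) {
  N <- length(catalog$universe)
  if (N == 0L) stopf("enrichment universe is empty")
  mm <- match_names(selected, catalog)
  sel <- mm$matched
  n <- length(sel)
  res <- lapply(names(catalog$pathways), function(pid) {
    set <- catalog$pathways[[pid]]
    K <- length(set)
    k <- length(intersect(sel, set))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = pid, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p), , drop = FALSE]
  out$q <- adjust_by(out$p, method = "BH")
  rownames(out) <- NULL
  attr(out, "unmatched") <- mm$unmatched
  out
}

#' Read a pathway catalog from TSV
#'
#' Format: `pathway_id TAB comma-separated metabolite names`, one pathway
#' per line.
#'
#' @param path file path
#' @param universe background metabolite names; defaults to the union of
#'   all pathway members
#' @return a `pathway_catalog`
#' @export
read_pathway_catalog <- function(path, universe = NULL) {
  if (!file.exists(path)) stopf("catalog file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  members <- lapply(parts, function(z)
    trimws(strsplit(if (length(z) > 1L) z[[2L]] else "", ",")[[1L]]))
  names(members) <- ids
  if (is.null(universe)) universe <- unique(unlist(members))
  pathway_catalog(members, universe)
}

#' Write a pathway catalog to TSV
#' @param catalog a `pathway_catalog`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pathway_catalog <- function(catalog, path) {
  lines <- vapply(names(catalog$pathways), function(pid)
    sprintf("%s\t%s", pid, paste(catalog$pathways[[pid]], collapse = ",")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
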
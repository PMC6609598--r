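#' Gene-set overlap test (right-tail Fisher exact)
#'
#' Cross-tabulates two gene sets against a background universe and tests
#' whether their intersection is larger than expected by chance, using the
#' right-tail (over-representation) Fisher exact test — equivalently the
#' upper hypergeometric tail including the observed count. The universe
#' size must be stated explicitly: overlap p-values are meaningless without
#' a declared background, and no default is defensible.
#'
#' @param set_a,set_b Character vectors of gene symbols (duplicates are
#'   removed).
#' @param universe_size Number of genes eligible for membership in either
#'   set; must be at least `|union(set_a, set_b)|`.
#'
#' @return One-row tibble: counts (`n_a`, `n_b`, `n_overlap`, `n_a_only`,
#'   `n_b_only`, `n_neither`), `percent_of_a` (share of set A covered by the
#'   overlap, 2 decimals), the sample `odds_ratio`, and `p_right`.
#' @export
#' @examples
#' overlap_test(letters[1:4], letters[3:6], universe_size = 26)
overlap_test <- function(set_a, set_b, universe_size) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  n_a <- length(set_a)
  n_b <- length(set_b)
  n_union <- length(union(set_a, set_b))
  if (universe_size < n_union) {
    abort("universe_size is smaller than the union of the two sets")
  }
  n_overlap <- length(intersect(set_a, set_b))
  counts_overlap_test(n_a, n_b, n_overlap, universe_size)
}

#' Overlap test from counts alone
#'
#' Same computation as [overlap_test()] when only the set sizes and
#' intersection count are known (e.g. from a published Venn diagram).
#'
#' @param n_a,n_b Set sizes.
#' @param n_overlap Intersection size.
#' @param universe_size Background universe size.
#' @return As [overlap_test()].
#' @export
counts_overlap_test <- function(n_a, n_b, n_overlap, universe_size) {
  if (n_overlap > min(n_a, n_b)) {
    abort("overlap cannot exceed either set size")
  }
  n_union <- n_a + n_b - n_overlap
  if (universe_size < n_union) {
    abort("universe_size is smaller than the union of the two sets")
  }
  a_only <- n_a - n_overlap
  b_only <- n_b - n_overlap
  neither <- universe_size - n_union
  # upper hypergeometric tail including the observed overlap
  p_right <- phyper(n_overlap - 1, n_a, universe_size - n_a, n_b,
                    lower.tail = FALSE)
  or <- (n_overlap * neither) / (a_only * b_only)
  tibble(
    n_a = n_a, n_b = n_b, n_overlap = n_overlap,
    n_a_only = a_only, n_b_only = b_only, n_neither = neither,
    percent_of_a = round(100 * n_overlap / n_a, 2),
    odds_ratio = or,
    p_right = p_right
  )
}

#' Over-representation analysis against a pathway collection
#'
#' For each pathway, tests whether the query gene list hits more pathway
#' members than expected under random sampling from the universe, via the
#' right-tail hypergeometric probability (the observed count included in
#' the tail, so a zero-hit pathway has p = 1). P-values are
#' Benjamini-Hochberg adjusted across all tested pathways.
#'
#' @param query Character vector of gene symbols.
#' @param collection Named list of pathway member vectors (see
#'   [read_gmt()]).
#' @param universe_size Background universe size; at least `|query|`.
#'
#' @return Tibble sorted by ascending `p` (ties broken by `pathway_id`)
#'   with `pathway_id`, `pathway_size`, `hits`, `p`, `q`.
#' @export
enrich <- function(query, collection, universe_size) {
  query <- unique(as.character(query))
  if (length(query) == 0) abort("query gene list is empty")
  if (!is.list(collection) || is.null(names(collection)) ||
      any(!nzchar(names(collection)))) {
    abort("collection must be a named list of pathways")
  }
  if (any(lengths(collection) == 0)) abort("pathways must be non-empty")
  if (universe_size < length(query)) {
    abort("universe_size is smaller than the query list")
  }
  sizes <- vapply(collection, function(s) length(unique(s)), integer(1))
  if (any(sizes > universe_size)) {
    abort("a pathway is larger than the universe")
  }
  hits <- vapply(collection, function(s)
    length(intersect(query, unique(s))), integer(1))
  p <- phyper(hits - 1, sizes, universe_size - sizes, length(query),
              lower.tail = FALSE)
  tibble(
    pathway_id = names(collection),
    pathway_size = unname(sizes),
    hits = unname(hits),
    p = unname(p),
    q = p.adjust(unname(p), method = "BH")
  ) |>
    arrange(.data$p, .data$pathway_id)
}

#' Read a gene list (one symbol per line)
#'
#' @param path Text file path.
#' @return Character vector of unique, non-empty symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readr::read_lines(path))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Read a GMT pathway collection
#'
#' Standard GMT: one pathway per line, tab-separated fields `name`,
#' `description`, then member genes.
#'
#' @param path GMT file path.
#' @return Named list of member-gene character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    abort(sprintf("malformed GMT line %d: fewer than 3 fields", bad[1]))
  }
  setNames(
    lapply(parts, function(x) unique(x[-(1:2)][nzchar(x[-(1:2)])])),
    vapply(parts, `[[`, character(1), 1)
  )
}
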
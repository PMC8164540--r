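# Hypergeometric gene-set enrichment. With M background genes, m of them
# prioritized, and a gene set overlapping the background in M_p genes and
# the prioritized list in m_p genes, the point probability of the observed
# overlap is C(M_p, m_p) * C(M - M_p, m - m_p) / C(M, m); enrichment uses
# the upper tail P(X >= m_p).

check_enrichment_counts <- function(M, m, M_p, m_p) {
  for (v in list(M = M, m = m, M_p = M_p, m_p = m_p)) {
    if (!is_count(v)) abort("Counts must be non-negative integers.")
  }
  if (m > M) abort("`m` cannot exceed the background size `M`.")
  if (M_p > M) abort("`M_p` cannot exceed the background size `M`.")
  if (m_p > min(m, M_p)) {
    abort("`m_p` cannot exceed min(m, M_p): impossible overlap.")
  }
  if (m - m_p > M - M_p) {
    abort("`m - m_p` cannot exceed `M - M_p`: impossible overlap.")
  }
  invisible(TRUE)
}

#' Hypergeometric point probability
#'
#' `P = C(M_p, m_p) * C(M - M_p, m - m_p) / C(M, m)`, evaluated in log-gamma
#' arithmetic (`lchoose`) so large counts stay exact to near machine
#' precision.
#'
#' @param M Background set size.
#' @param m Prioritized set size (`m <= M`).
#' @param M_p Overlap of the gene set with the background.
#' @param m_p Overlap of the gene set with the prioritized list.
#' @return The point probability in `[0, 1]`.
#' @examples
#' hypergeom_point(M = 20, m = 5, M_p = 8, m_p = 4)
#' @export
hypergeom_point <- function(M, m, M_p, m_p) {
  check_enrichment_counts(M, m, M_p, m_p)
  exp(lchoose(M_p, m_p) + lchoose(M - M_p, m - m_p) - lchoose(M, m))
}

#' Enrichment test for one gene set
#'
#' `mode = "tail"` (default) returns the upper-tail enrichment probability
#' `P(X >= m_p) = sum_k P(X = k)` for `k` from `m_p` to `min(m, M_p)`; this
#' is the standard over-representation test. `mode = "point"` returns the
#' point probability of exactly the observed overlap.
#'
#' @param prioritized Character vector of prioritized gene ids (must be a
#'   subset of `background`), or `NULL` when counts are given directly.
#' @param background Character vector of background gene ids.
#' @param gene_set Character vector of gene-set members.
#' @param mode `"tail"` or `"point"`.
#' @param counts Optional named list/vector with `M`, `m`, `M_p`, `m_p`,
#'   bypassing the id sets.
#' @return A one-row tibble with `M`, `m`, `M_p`, `m_p`, `p_value`.
#' @examples
#' enrich_test(counts = c(M = 20, m = 5, M_p = 8, m_p = 4))
#' @export
enrich_test <- function(prioritized = NULL, background = NULL,
                        gene_set = NULL, mode = c("tail", "point"),
                        counts = NULL) {
  mode <- match.arg(mode)
  if (is.null(counts)) {
    if (is.null(prioritized) || is.null(background) || is.null(gene_set)) {
      abort("Provide gene id sets or explicit `counts`.")
    }
    background <- unique(background)
    prioritized <- unique(prioritized)
    gene_set <- unique(gene_set)
    if (!all(prioritized %in% background)) {
      abort("`prioritized` must be a subset of `background`.")
    }
    counts <- c(
      M = length(background), m = length(prioritized),
      M_p = length(intersect(gene_set, background)),
      m_p = length(intersect(gene_set, prioritized))
    )
  }
  counts <- as.list(counts)
  M <- counts$M; m <- counts$m; M_p <- counts$M_p; m_p <- counts$m_p
  check_enrichment_counts(M, m, M_p, m_p)
  p <- if (mode == "point") {
    hypergeom_point(M, m, M_p, m_p)
  } else {
    ks <- seq.int(m_p, min(m, M_p))
    min(sum(vapply(ks, function(k) hypergeom_point(M, m, M_p, k),
                   numeric(1L))), 1)
  }
  tibble::tibble(M = M, m = m, M_p = M_p, m_p = m_p, p_value = p)
}

#' Enrichment over a collection of gene sets
#'
#' Runs [enrich_test()] for every named gene set and returns one row per
#' set, sorted by ascending p-value (ties by set name). Gene sets disjoint
#' from the background get `M_p = 0` and `p_value = 1` in tail mode.
#' Benjamini-Hochberg adjustment is offered but off by default, matching
#' the common practice of raw p-value cutoffs for this test.
#'
#' @param prioritized,background Character vectors of gene ids.
#' @param collection Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param mode `"tail"` or `"point"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble with `set_name`, counts, `p_value`, `p_adjusted`.
#' @export
enrich_collection <- function(prioritized, background, collection,
                              mode = c("tail", "point"),
                              adjust = c("none", "BH")) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  if (!is.list(collection) || length(collection) == 0L ||
      is.null(names(collection)) || any(names(collection) == "")) {
    abort("`collection` must be a non-empty named list of gene sets.")
  }
  rows <- purrr::imap(collection, function(genes, nm) {
    dplyr::mutate(
      enrich_test(prioritized, background, genes, mode = mode),
      set_name = nm, .before = 1L
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- if (adjust == "BH") {
    p.adjust(out$p_value, method = "BH")
  } else {
    out$p_value
  }
  dplyr::arrange(out, .data$p_value, .data$set_name)
}

#' Read gene sets from a GMT file
#'
#' GMT is line-based: set name, description, then tab-separated gene ids.
#' Duplicate genes within a set are removed with a warning; lines with
#' fewer than three fields raise an error naming the line number.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("GMT file is empty: %s", path))
  out <- list()
  for (k in seq_along(lines)) {
    fields <- strsplit(lines[k], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      abort(sprintf("Malformed GMT line %d in %s: needs name, description and >= 1 gene.",
                    k, path))
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warn(sprintf("Duplicate gene ids in set '%s' (GMT line %d); deduplicated.",
                   fields[1L], k))
      genes <- unique(genes)
    }
    out[[fields[1L]]] <- genes
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param collection Named list of character vectors.
#' @param path Output path.
#' @param description Optional description column (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, description = "") {
  stopifnot(is.list(collection), !is.null(names(collection)))
  description <- rep_len(description, length(collection))
  lines <- vapply(seq_along(collection), function(k) {
    paste(c(names(collection)[k], description[k], collection[[k]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
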
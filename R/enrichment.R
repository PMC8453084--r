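#' Read / write gene sets in GMT format
#'
#' GMT is tab-separated: term, description, then member gene ids. Duplicate
#' genes within a term are dropped with a warning; a line with fewer than
#' three fields is a parse error reporting the line number.
#'
#' @param path GMT file path.
#' @return `read_gmt()`: named list of character vectors (class `gene_sets`)
#'   with a `description` attribute; `write_gmt()` returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0)
    stop(sprintf("malformed GMT line %d: fewer than 3 fields", bad[1]))
  sets <- lapply(seq_along(fields), function(i) {
    genes <- fields[[i]][-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("term %s: duplicate genes deduplicated", fields[[i]][1]))
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- vapply(fields, `[`, character(1), 1)
  attr(sets, "description") <- vapply(fields, `[`, character(1), 2)
  class(sets) <- "gene_sets"
  sets
}

#' @rdname read_gmt
#' @param gene_sets named list of character vectors; an optional
#'   `description` attribute supplies the second column.
#' @export
write_gmt <- function(gene_sets, path) {
  desc <- attr(gene_sets, "description")
  if (is.null(desc)) desc <- rep("", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], desc[i], gene_sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` of drawing `k` or more term genes when
#' `n` genes are drawn without replacement from a universe of `N` genes of
#' which `K` belong to the term.
#'
#' @param k observed overlap.
#' @param n gene-list size.
#' @param K term size.
#' @param N universe size.
#' @return the exact tail probability.
#' @export
hypergeometric_test <- function(k, n, K, N) {
  if (k < 0 || K > N || n > N || k > min(n, K))
    stop("inconsistent counts: need 0 <= k <= min(n, K) <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up procedure with monotonicity enforcement, returned in the
#' input order.
#'
#' @param p_values p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a gene list against gene sets
#'
#' One hypergeometric test per term (term membership intersected with the
#' universe), BH-adjusted across terms, ranked by p. List genes absent from
#' the universe are dropped (count reported via `message`).
#'
#' @param gene_list character vector of genes of interest.
#' @param gene_sets a `gene_sets` collection (see [read_gmt()]).
#' @param universe character vector of background genes.
#' @param alpha significance threshold on the q-value, default 0.05.
#' @return data.frame ranked by p: `term`, `term_size` (K), `list_size` (n),
#'   `universe_size` (N), `overlap` (k), `overlap_genes`
#'   (semicolon-separated), `p`, `q`, `significant`.
#' @export
run_ora <- function(gene_list, gene_sets, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  dropped <- sum(!gene_list %in% universe)
  if (dropped > 0)
    message(sprintf("dropping %d list gene(s) absent from the universe",
                    dropped))
  gl <- unique(gene_list[gene_list %in% universe])
  if (length(gl) == 0) stop("empty gene list after universe filtering")
  N <- length(universe)
  n <- length(gl)
  rows <- lapply(seq_along(gene_sets), function(i) {
    term_genes <- intersect(unique(gene_sets[[i]]), universe)
    hit <- intersect(gl, term_genes)
    data.frame(term = names(gene_sets)[i], term_size = length(term_genes),
               list_size = n, universe_size = N, overlap = length(hit),
               overlap_genes = paste(sort(hit), collapse = ";"),
               p = hypergeometric_test(length(hit), n, length(term_genes), N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < alpha
  out <- out[order(out$p, -out$overlap), ]
  rownames(out) <- NULL
  out
}
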
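#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated member symbols.
#'
#' @param path path to a GMT file.
#' @return A named list of character vectors of (uppercased) gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("GMT file not found: ", path))
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) rlang::abort(paste0(path, ": no gene sets"))
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      rlang::abort(paste0(path, ": malformed GMT line: ", substr(l, 1, 40)))
    }
    unique(normalize_symbols(parts[-(1:2)]))
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(sets))) {
    rlang::abort(paste0(path, ": duplicate gene-set names"))
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field per set (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set overrepresentation analysis
#'
#' For each gene set, tests whether the query gene list overlaps the set
#' more than expected under sampling without replacement from the universe.
#' With universe size N, set size K (within the universe), query size n
#' (within the universe) and overlap k, the p-value is the upper tail
#' \deqn{p = P(X \ge k) = \sum_{i=k}^{\min(n,K)}
#'   \binom{K}{i}\binom{N-K}{n-i} \big/ \binom{N}{n}.}
#' One-sided overrepresentation only; Benjamini-Hochberg q-values are
#' computed across all tested sets.
#'
#' @param query character vector of gene symbols (intersected with the
#'   universe before testing).
#' @param sets named list of gene sets (e.g. from [read_gmt()]); sets with
#'   no member in the universe are dropped with a message.
#' @param universe background gene symbols, e.g. all genes in the receiver
#'   expression table.
#' @param alpha significance level for the `significant` flag on the raw
#'   p-value (default 0.05).
#' @return A tibble sorted by p ascending (ties by set name): `set`, `k`
#'   (overlap), `K` (set size in universe), `n` (query size in universe),
#'   `N` (universe size), `p`, `q`, `significant`.
#' @examples
#' overrepresentation(letters[1:5],
#'                    list(s = letters[1:5]),
#'                    universe = letters[1:10])$p # 1/choose(10, 5)
#' @export
overrepresentation <- function(query, sets, universe, alpha = 0.05) {
  universe <- unique(normalize_symbols(universe))
  if (length(universe) == 0L) rlang::abort("empty universe")
  query <- intersect(unique(normalize_symbols(query)), universe)
  if (length(query) == 0L) {
    rlang::abort("query has no genes in the universe")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    rlang::abort("gene sets must be named")
  }
  sets <- lapply(sets, function(s) intersect(unique(normalize_symbols(s)), universe))
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty) > 0L) {
    message("dropping ", length(empty),
            " gene set(s) with no members in the universe")
    sets <- sets[lengths(sets) > 0L]
  }
  if (length(sets) == 0L) rlang::abort("no gene sets left after intersection")
  N <- length(universe)
  n <- length(query)
  res <- tibble::tibble(
    set = names(sets),
    k = unname(vapply(sets, function(s) length(intersect(query, s)), integer(1))),
    K = unname(lengths(sets)),
    n = n,
    N = N
  )
  # P(X >= k) via the complementary lower tail
  res$p <- stats::phyper(res$k - 1, m = res$K, n = N - res$K, k = n,
                         lower.tail = FALSE)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p < alpha
  dplyr::arrange(res, .data$p, .data$set)
}
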
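#' Screen configuration: expression cutoffs and ranking depth
#'
#' Bundles the TPM cutoffs that drive every classification in the screen.
#' All comparisons in the package are *strict* inequalities: a gene whose
#' mean TPM is exactly equal to a cutoff falls in the lower tier.
#'
#' @param expressed_cutoff TPM above which a gene counts as expressed
#'   (default 2).
#' @param high_cutoff TPM above which a gene counts as highly expressed
#'   (default 10, i.e. log10 TPM > 1).
#' @param ligand_plot_cutoff sender-tissue TPM a ligand must exceed for its
#'   pair to be drawn in quadrant scatter plots (default 1).
#' @param very_high_cutoff TPM above which a gene counts as very highly
#'   expressed (default 100).
#' @param top_n how many genes the top-expression rankings keep (default 50).
#'
#' @return A list of class `screen_config`.
#' @examples
#' cfg <- screen_config()
#' cfg$high_cutoff
#' @export
screen_config <- function(expressed_cutoff = 2,
                          high_cutoff = 10,
                          ligand_plot_cutoff = 1,
                          very_high_cutoff = 100,
                          top_n = 50) {
  for (v in c("expressed_cutoff", "high_cutoff", "ligand_plot_cutoff",
              "very_high_cutoff", "top_n")) {
    x <- get(v)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      rlang::abort(paste0("`", v, "` must be a single finite number"))
    }
  }
  if (!(ligand_plot_cutoff > 0 &&
        ligand_plot_cutoff <= expressed_cutoff &&
        expressed_cutoff < high_cutoff &&
        high_cutoff < very_high_cutoff)) {
    rlang::abort(
      "cutoffs must satisfy 0 < ligand_plot_cutoff <= expressed_cutoff < high_cutoff < very_high_cutoff"
    )
  }
  if (top_n < 1 || top_n != as.integer(top_n)) {
    rlang::abort("`top_n` must be an integer >= 1")
  }
  structure(
    list(
      expressed_cutoff = expressed_cutoff,
      high_cutoff = high_cutoff,
      ligand_plot_cutoff = ligand_plot_cutoff,
      very_high_cutoff = very_high_cutoff,
      top_n = as.integer(top_n)
    ),
    class = "screen_config"
  )
}

#' @export
print.screen_config <- function(x, ...) {
  cat("<screen_config>\n")
  cat("  expressed   : TPM >", x$expressed_cutoff, "\n")
  cat("  high        : TPM >", x$high_cutoff, "\n")
  cat("  very high   : TPM >", x$very_high_cutoff, "\n")
  cat("  ligand plot : TPM >", x$ligand_plot_cutoff, "\n")
  cat("  top_n       :", x$top_n, "\n")
  invisible(x)
}

normalize_symbols <- function(x) toupper(trimws(as.character(x)))

sample_columns <- function(tbl) {
  setdiff(names(tbl), c("gene", "length_kb"))
}

validate_expression <- function(tbl, counts = FALSE,
                                what = if (counts) "count table" else "expression matrix") {
  if (!is.data.frame(tbl) || nrow(tbl) == 0L) {
    rlang::abort(paste0("empty ", what))
  }
  if (!identical(names(tbl)[1], "gene")) {
    rlang::abort(paste0(what, ": first column must be `gene`"))
  }
  if (counts && !"length_kb" %in% names(tbl)) {
    rlang::abort(paste0(what, ": missing `length_kb` column (counts mode)"))
  }
  samples <- sample_columns(tbl)
  if (length(samples) == 0L) {
    rlang::abort(paste0(what, ": no sample columns"))
  }
  genes <- normalize_symbols(tbl$gene)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0L) {
    rlang::abort(paste0(what, ": duplicate gene symbols: ",
                        paste(utils::head(dup, 5), collapse = ", ")))
  }
  for (s in samples) {
    col <- tbl[[s]]
    if (!is.numeric(col)) {
      rlang::abort(paste0(what, ": sample column `", s, "` is not numeric"))
    }
    if (anyNA(col) || any(col < 0)) {
      rlang::abort(paste0(what, ": sample `", s, "` has missing or negative values"))
    }
  }
  if (counts) {
    len <- tbl$length_kb
    if (!is.numeric(len) || anyNA(len) || any(len <= 0)) {
      rlang::abort("count table: all `length_kb` values must be > 0")
    }
  }
  invisible(tbl)
}

#' Convert read counts to transcripts per million (TPM)
#'
#' Per sample, each gene's count is divided by its transcript length in
#' kilobases to give a length-normalized rate, and the rates are rescaled so
#' they sum to one million:
#' \deqn{\mathrm{TPM}_i = 10^6 \, \frac{c_i / \ell_i}{\sum_j c_j / \ell_j}}
#' where \eqn{c_i} is the read count and \eqn{\ell_i} the length in kb.
#'
#' @param counts A data frame with columns `gene`, `length_kb` and one
#'   numeric column per sample (non-negative integers).
#' @return A tibble with `gene` plus one TPM column per sample; every sample
#'   column sums to 1e6 (up to rounding). Carries attribute
#'   `provenance = "from_counts"`.
#' @examples
#' tpm <- compute_tpm(tibble::tibble(
#'   gene = c("A", "B"), length_kb = c(1, 2), s1 = c(10, 10)
#' ))
#' sum(tpm$s1) # 1e6
#' @export
compute_tpm <- function(counts) {
  counts <- tibble::as_tibble(counts)
  validate_expression(counts, counts = TRUE)
  counts$gene <- normalize_symbols(counts$gene)
  samples <- sample_columns(counts)
  zero <- samples[vapply(samples, function(s) all(counts[[s]] == 0), logical(1))]
  if (length(zero) > 0L) {
    rlang::abort(paste0("sample(s) with all-zero counts: ",
                        paste(zero, collapse = ", ")))
  }
  out <- tibble::tibble(gene = counts$gene)
  for (s in samples) {
    rate <- counts[[s]] / counts$length_kb
    out[[s]] <- 1e6 * rate / sum(rate)
  }
  attr(out, "provenance") <- "from_counts"
  out
}

#' Read an expression table from TSV
#'
#' Reads either a TPM matrix (`gene` column followed by sample columns) or a
#' count table (`gene`, `length_kb`, then sample columns). Gene symbols are
#' uppercased; matching elsewhere in the package is case-insensitive by
#' construction. In counts mode the table is converted to TPM with
#' [compute_tpm()].
#'
#' @param path path to a UTF-8 TSV file with a header row.
#' @param mode `"tpm"` (values used as-is, never renormalized) or
#'   `"counts"` (converted to TPM).
#' @param duplicates what to do with duplicate gene symbols after
#'   uppercasing: `"error"` (default), `"sum"` (counts mode) or `"max"`
#'   (TPM mode). Non-default policies emit a message naming the symbols.
#' @return A tibble of TPM values with attribute `provenance` set to
#'   `"supplied_tpm"` or `"from_counts"`.
#' @export
read_expression <- function(path, mode = c("tpm", "counts"),
                            duplicates = c("error", "sum", "max")) {
  mode <- rlang::arg_match(mode)
  duplicates <- rlang::arg_match(duplicates)
  if (!file.exists(path)) {
    rlang::abort(paste0("expression file not found: ", path))
  }
  tbl <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    gene = readr::col_character()
  ), progress = FALSE))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0L) {
    rlang::abort(paste0(
      "parse error in ", path, " at line ", probs$row[1],
      ": expected ", probs$expected[1], ", got '", probs$actual[1], "'"
    ))
  }
  if (!"gene" %in% names(tbl)) {
    rlang::abort(paste0(path, ": missing `gene` header column"))
  }
  tbl <- dplyr::relocate(tbl, "gene")
  tbl$gene <- normalize_symbols(tbl$gene)
  if (mode == "counts" && !"length_kb" %in% names(tbl)) {
    rlang::abort(paste0(path, ": counts mode requires a `length_kb` column"))
  }
  if (mode == "counts") tbl <- dplyr::relocate(tbl, "length_kb", .after = "gene")
  if (length(sample_columns(tbl)) == 0L) {
    rlang::abort(paste0(path, ": no sample columns"))
  }

  dup <- unique(tbl$gene[duplicated(tbl$gene)])
  if (length(dup) > 0L) {
    if (duplicates == "error") {
      first_line <- which(duplicated(tbl$gene))[1] + 1L # + header
      rlang::abort(paste0(path, ": duplicate gene symbol `",
                          tbl$gene[duplicated(tbl$gene)][1],
                          "` at line ", first_line,
                          " (set `duplicates` to resolve)"))
    }
    if (duplicates == "sum" && mode != "counts") {
      rlang::abort("duplicates = \"sum\" is only meaningful in counts mode")
    }
    if (duplicates == "max" && mode != "tpm") {
      rlang::abort("duplicates = \"max\" is only meaningful in tpm mode")
    }
    message("resolving ", length(dup), " duplicate symbol(s) by ",
            duplicates, ": ", paste(utils::head(dup, 10), collapse = ", "))
    samples <- sample_columns(tbl)
    if (duplicates == "sum") {
      tbl <- tbl |>
        dplyr::group_by(.data$gene) |>
        dplyr::summarise(
          length_kb = .data$length_kb[1],
          dplyr::across(dplyr::all_of(samples), sum),
          .groups = "drop"
        )
    } else {
      tbl <- tbl |>
        dplyr::mutate(.row_mean = rowMeans(dplyr::pick(dplyr::all_of(samples)))) |>
        dplyr::group_by(.data$gene) |>
        dplyr::arrange(dplyr::desc(.data$.row_mean), .by_group = TRUE) |>
        dplyr::slice(1) |>
        dplyr::ungroup() |>
        dplyr::select(-".row_mean")
    }
  }

  if (mode == "counts") {
    compute_tpm(tbl)
  } else {
    validate_expression(tbl)
    attr(tbl, "provenance") <- "supplied_tpm"
    tbl
  }
}

#' Summarize genes: replicate means and expression tiers
#'
#' Averages TPM across replicates (unweighted arithmetic mean) and flags each
#' gene against the configured cutoffs with strict inequalities, so e.g. a
#' mean of exactly 2 TPM is *not* expressed under the default cutoff of 2.
#'
#' @param tpm A TPM tibble (`gene` plus sample columns), e.g. from
#'   [read_expression()] or [compute_tpm()].
#' @param config A [screen_config()].
#' @return A tibble with one row per gene: `gene`, `mean_tpm`, `n_samples`,
#'   and logical `expressed`, `high`, `very_high`.
#' @examples
#' tpm <- tibble::tibble(gene = "NPR2", s1 = 1, s2 = 3, s3 = 2, s4 = 2)
#' summarize_genes(tpm)$expressed # FALSE: mean 2 is not > 2
#' @export
summarize_genes <- function(tpm, config = screen_config()) {
  tpm <- tibble::as_tibble(tpm)
  validate_expression(tpm)
  stopifnot(inherits(config, "screen_config"))
  samples <- sample_columns(tpm)
  tibble::tibble(
    gene = normalize_symbols(tpm$gene),
    mean_tpm = rowMeans(as.matrix(tpm[samples])),
    n_samples = length(samples)
  ) |>
    dplyr::mutate(
      expressed = .data$mean_tpm > config$expressed_cutoff,
      high = .data$mean_tpm > config$high_cutoff,
      very_high = .data$mean_tpm > config$very_high_cutoff
    )
}
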
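quadrant_levels <- c("high_high", "high_low", "low_high", "low_low")

#' Classify a receptor/ligand TPM pair into an expression quadrant
#'
#' Pairs are split four ways by whether the receiver-tissue receptor mean TPM
#' and the sender-tissue ligand mean TPM each exceed the high-expression
#' cutoff (default 10 TPM, strict): `high_high`, `high_low` (receptor high,
#' ligand not), `low_high`, `low_low`.
#'
#' @param receptor_tpm,ligand_tpm non-negative numeric vectors (recycled).
#' @param config A [screen_config()].
#' @return Character vector of quadrant labels.
#' @examples
#' assign_quadrant(15, 12) # "high_high"
#' assign_quadrant(10, 12) # "low_high": 10 is not > 10
#' @export
assign_quadrant <- function(receptor_tpm, ligand_tpm, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  if (any(receptor_tpm < 0, na.rm = TRUE) || any(ligand_tpm < 0, na.rm = TRUE)) {
    rlang::abort("TPM values must be non-negative")
  }
  r_hi <- receptor_tpm > config$high_cutoff
  l_hi <- ligand_tpm > config$high_cutoff
  dplyr::case_when(
    r_hi & l_hi ~ "high_high",
    r_hi & !l_hi ~ "high_low",
    !r_hi & l_hi ~ "low_high",
    .default = "low_low"
  )
}

#' Identify expressed receptor genes in the receiver tissue
#'
#' The receptor universe is the set of receptor symbols in the pair database
#' plus any curation force-includes, minus curation excludes. A receptor is
#' retained when its receiver-tissue mean TPM strictly exceeds the expressed
#' cutoff. Each record carries the union of the categories of its pairs, a
#' nested tibble of its annotated ligands, and an orphan flag (no annotated
#' ligand).
#'
#' @param receiver_summary gene summaries of the receiver tissue, from
#'   [summarize_genes()].
#' @param db validated pair-database tibble.
#' @param curation optional [curation_list()].
#' @param config A [screen_config()].
#' @return A tibble sorted by `mean_tpm` descending (ties by symbol):
#'   `gene`, `mean_tpm`, `categories`, `n_ligands`, `orphan`, `high`,
#'   `very_high`, and list-column `ligands`.
#' @export
identify_receptors <- function(receiver_summary, db, curation = NULL,
                               config = screen_config()) {
  db <- validate_pair_db(db)
  stopifnot(inherits(config, "screen_config"))
  universe <- apply_curation(unique(db$receptor), curation)
  hits <- receiver_summary |>
    dplyr::filter(.data$gene %in% universe,
                  .data$mean_tpm > config$expressed_cutoff)
  lig <- purrr::map(hits$gene, ligands_of, db = db)
  cats <- purrr::map_chr(lig, function(l) {
    toks <- unique(unlist(strsplit(l$categories, ";", fixed = TRUE)))
    paste(sort(toks), collapse = ";")
  })
  tibble::tibble(
    gene = hits$gene,
    mean_tpm = hits$mean_tpm,
    categories = cats,
    n_ligands = vapply(lig, nrow, integer(1)),
    orphan = vapply(lig, nrow, integer(1)) == 0L,
    high = hits$mean_tpm > config$high_cutoff,
    very_high = hits$mean_tpm > config$very_high_cutoff,
    ligands = lig
  ) |>
    dplyr::arrange(dplyr::desc(.data$mean_tpm), .data$gene)
}

#' Build the receptor-ligand pair table
#'
#' One row per (expressed receptor, annotated ligand, pair category). The
#' ligand's sender-tissue mean TPM is looked up in the sender summaries; a
#' ligand gene absent from the sender table gets TPM 0 with
#' `ligand_missing = TRUE` rather than being dropped. Each row carries its
#' expression quadrant and a `plotted` flag implementing the figure
#' inclusion rule (receptor TPM > expressed cutoff AND ligand TPM >
#' ligand-plot cutoff).
#'
#' @param receptors receptor records from [identify_receptors()].
#' @param sender_summary gene summaries of the sender tissue.
#' @param db validated pair-database tibble.
#' @param config A [screen_config()].
#' @return A tibble ordered by (category, receptor, ligand): `category`,
#'   `receptor`, `receptor_tpm`, `ligand`, `ligand_kind`, `molecule`,
#'   `ligand_tpm`, `ligand_missing`, `quadrant`, `plotted`.
#' @export
build_pair_table <- function(receptors, sender_summary, db,
                             config = screen_config()) {
  db <- validate_pair_db(db)
  stopifnot(inherits(config, "screen_config"))
  edges <- db |>
    dplyr::filter(.data$receptor %in% receptors$gene) |>
    tidyr::separate_longer_delim("categories", ";") |>
    dplyr::rename(category = "categories")
  sender_tpm <- stats::setNames(sender_summary$mean_tpm, sender_summary$gene)
  receptor_tpm <- stats::setNames(receptors$mean_tpm, receptors$gene)
  edges |>
    dplyr::mutate(
      receptor_tpm = unname(receptor_tpm[.data$receptor]),
      ligand_missing = !(.data$ligand %in% names(sender_tpm)),
      ligand_tpm = ifelse(.data$ligand_missing, 0,
                          unname(sender_tpm[.data$ligand])),
      quadrant = assign_quadrant(.data$receptor_tpm, .data$ligand_tpm, config),
      plotted = .data$receptor_tpm > config$expressed_cutoff &
        .data$ligand_tpm > config$ligand_plot_cutoff
    ) |>
    dplyr::select("category", "receptor", "receptor_tpm", "ligand",
                  "ligand_kind", "molecule", "ligand_tpm", "ligand_missing",
                  "quadrant", "plotted") |>
    dplyr::arrange(.data$category, .data$receptor, .data$ligand)
}

#' Count pairs per expression quadrant
#'
#' Counts every pair of the category over the four quadrants, irrespective of
#' the plot-inclusion flag (which only governs what the scatter figures
#' display); set `plotted_only = TRUE` for figure parity. The four counts
#' always sum to the category's pair total.
#'
#' @param pairs pair table from [build_pair_table()].
#' @param category one category token, or `NULL` to count across all pairs.
#' @param plotted_only count only pairs passing the plot-inclusion rule.
#' @return A named integer vector over `high_high`, `high_low`, `low_high`,
#'   `low_low`.
#' @export
count_quadrants <- function(pairs, category = NULL, plotted_only = FALSE) {
  if (!is.null(category)) {
    if (!category %in% lr_categories) {
      rlang::abort(paste0("unknown category `", category, "`"))
    }
    pairs <- dplyr::filter(pairs, .data$category == !!category)
  }
  if (plotted_only) pairs <- dplyr::filter(pairs, .data$plotted)
  counts <- table(factor(pairs$quadrant, levels = quadrant_levels))
  stats::setNames(as.integer(counts), quadrant_levels)
}

#' Top-N genes by mean expression
#'
#' Descending by `mean_tpm`; ties broken by gene symbol ascending so the
#' ranking is deterministic. Returns the whole (sorted) input when `n`
#' exceeds its size.
#'
#' @param summaries a tibble with `gene` and `mean_tpm` columns (gene
#'   summaries or receptor records).
#' @param n how many genes to keep (default from `config`-less use: 50).
#' @return The top-`n` rows, sorted.
#' @export
rank_top <- function(summaries, n = 50) {
  stopifnot(n >= 1)
  summaries |>
    dplyr::arrange(dplyr::desc(.data$mean_tpm), .data$gene) |>
    utils::head(n)
}

#' Expressed receptors with no annotated ligand
#'
#' @param receptors receptor records from [identify_receptors()].
#' @return The orphan records, sorted by `mean_tpm` descending.
#' @export
find_orphans <- function(receptors) {
  receptors |>
    dplyr::filter(.data$orphan) |>
    dplyr::arrange(dplyr::desc(.data$mean_tpm), .data$gene)
}

#' Inventory ligand genes expressed by the receiver tissue
#'
#' The autocrine/paracrine inventory: genes that appear as *protein* ligand
#' genes in the pair database (synthesis-enzyme proxies are excluded — they
#' encode enzymes, not ligands) and whose receiver-tissue mean TPM exceeds
#' the expressed cutoff.
#'
#' @param receiver_summary gene summaries of the receiver tissue.
#' @param db validated pair-database tibble.
#' @param config A [screen_config()].
#' @return Gene summaries of the expressed ligand genes, ranked descending.
#' @export
identify_ligand_genes <- function(receiver_summary, db,
                                  config = screen_config()) {
  db <- validate_pair_db(db)
  ligand_genes <- unique(db$ligand[db$ligand_kind == "protein"])
  receiver_summary |>
    dplyr::filter(.data$gene %in% ligand_genes,
                  .data$mean_tpm > config$expressed_cutoff) |>
    dplyr::arrange(dplyr::desc(.data$mean_tpm), .data$gene)
}

#' Run the full cross-tissue ligand-receptor screen
#'
#' Chains the whole analysis: summarize both tissues, identify expressed
#' receptors in the receiver, build the pair table against sender ligand
#' expression, count quadrants per category, rank top receptors and
#' autocrine ligands, and list orphans.
#'
#' Quadrant headline counts exclude synthesis-enzyme-proxy pairs (their
#' quadrants are computed on the proxy gene's expression and reported in the
#' separate proxy panel); plotted-only counts are stored alongside for
#' figure parity.
#'
#' @param receiver,sender TPM tibbles (`gene` plus sample columns) for the
#'   receptor-bearing and ligand-producing tissue respectively.
#' @param db pair database (default: the shipped curated fixture).
#' @param curation optional [curation_list()].
#' @param config A [screen_config()].
#' @return An object of class `lr_atlas`: a list with elements
#'   `receptors`, `pairs`, `quadrant_counts`, `top_receptors`,
#'   `autocrine_ligands`, `top_autocrine`, `orphans`, `receiver_summary`,
#'   `sender_summary`, `missing_ligands`, `config`.
#' @examples
#' sim <- simulate_crosstalk(sim_config(n_genes = 300, seed = 1))
#' atlas <- lr_screen(sim$receiver, sim$sender, db = sim$pairs,
#'                    curation = sim$curation)
#' glance(atlas)
#' @export
lr_screen <- function(receiver, sender, db = default_pair_db(),
                      curation = NULL, config = screen_config()) {
  db <- validate_pair_db(db)
  receiver_summary <- summarize_genes(receiver, config)
  sender_summary <- summarize_genes(sender, config)
  receptors <- identify_receptors(receiver_summary, db, curation, config)
  pairs <- build_pair_table(receptors, sender_summary, db, config)
  protein_pairs <- dplyr::filter(pairs, .data$ligand_kind == "protein")
  proxy_pairs <- dplyr::filter(pairs, .data$ligand_kind == "synthesis_enzyme_proxy")
  quadrant_counts <- purrr::map_dfr(lr_categories, function(cat) {
    tibble::tibble(
      category = cat,
      quadrant = quadrant_levels,
      n_all = unname(count_quadrants(pairs, cat)),
      n_protein = unname(count_quadrants(
        protein_pairs[protein_pairs$category == cat, ], NULL)),
      n_plotted = unname(count_quadrants(pairs, cat, plotted_only = TRUE))
    )
  })
  autocrine <- identify_ligand_genes(receiver_summary, db, config)
  missing <- sort(unique(pairs$ligand[pairs$ligand_missing]))
  if (length(missing) > 0L) {
    message(length(missing), " ligand gene(s) absent from the sender table ",
            "(TPM set to 0): ", paste(utils::head(missing, 10), collapse = ", "))
  }
  structure(
    list(
      receptors = receptors,
      pairs = pairs,
      quadrant_counts = quadrant_counts,
      top_receptors = rank_top(receptors, config$top_n),
      autocrine_ligands = autocrine,
      top_autocrine = rank_top(autocrine, config$top_n),
      orphans = find_orphans(receptors),
      receiver_summary = receiver_summary,
      sender_summary = sender_summary,
      missing_ligands = missing,
      config = config
    ),
    class = "lr_atlas"
  )
}

#' @export
print.lr_atlas <- function(x, ...) {
  hh <- x$quadrant_counts |>
    dplyr::filter(.data$quadrant == "high_high",
                  .data$category != "small_molecule")
  cat("<lr_atlas>\n")
  cat("  expressed receptors :", nrow(x$receptors),
      sprintf("(of which %d orphan)\n", nrow(x$orphans)))
  cat("  receptor-ligand pairs:", nrow(x$pairs), "\n")
  cat("  high/high pairs (protein ligands):",
      paste(sprintf("%s=%d", hh$category, hh$n_protein), collapse = ", "), "\n")
  cat("  autocrine ligand genes:", nrow(x$autocrine_ligands), "\n")
  invisible(x)
}

#' Tidy the pair table of an atlas
#'
#' @param x an `lr_atlas` from [lr_screen()].
#' @param ... unused.
#' @return The pair tibble (one row per receptor-ligand-category edge).
#' @importFrom generics tidy
#' @export
tidy.lr_atlas <- function(x, ...) x$pairs

#' One-row summary of an atlas
#'
#' @param x an `lr_atlas` from [lr_screen()].
#' @param ... unused.
#' @return A one-row tibble of headline counts: receptors, orphans,
#'   autocrine ligands, very-high receptors, pairs, and the high/high pair
#'   count over protein-ligand pairs.
#' @importFrom generics glance
#' @export
glance.lr_atlas <- function(x, ...) {
  protein_hh <- x$quadrant_counts |>
    dplyr::filter(.data$quadrant == "high_high") |>
    dplyr::summarise(n = sum(.data$n_protein)) |>
    dplyr::pull("n")
  tibble::tibble(
    n_receptors = nrow(x$receptors),
    n_orphans = nrow(x$orphans),
    n_autocrine_ligands = nrow(x$autocrine_ligands),
    n_very_high_receptors = sum(x$receptors$very_high),
    n_pairs = nrow(x$pairs),
    n_high_high_protein = protein_hh
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
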
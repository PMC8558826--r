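#' Bar chart of the most highly expressed genes
#'
#' Horizontal bar chart of mean TPM for the top-`n` genes of a summary or
#' receptor table, mirroring atlas-style transcript-abundance figures.
#'
#' @param summaries tibble with `gene` and `mean_tpm`.
#' @param n how many genes to show (default 50).
#' @param title plot title.
#' @return A ggplot object.
#' @export
plot_top_genes <- function(summaries, n = 50, title = "Most highly expressed genes") {
  top <- rank_top(summaries, n)
  ggplot2::ggplot(top, ggplot2::aes(
    x = .data$mean_tpm,
    y = stats::reorder(.data$gene, .data$mean_tpm)
  )) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "Mean TPM", y = NULL, title = title) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Quadrant scatter of receptor vs ligand expression for one category
#'
#' log10 receiver-tissue receptor TPM (y) against log10 sender-tissue ligand
#' TPM (x), restricted to pairs passing the plot-inclusion rule (receptor
#' TPM above the expressed cutoff and ligand TPM above the ligand-plot
#' cutoff, so no pseudo-count is ever needed on the log axes). Dashed lines
#' mark the high-expression cutoff on both axes; points beyond both lines
#' are the high/high pairs.
#'
#' @param atlas an `lr_atlas` from [lr_screen()].
#' @param category one pair category.
#' @param zoom if `TRUE`, show only the high/high pairs, labelled, as in
#'   the zoomed identification panels.
#' @return A ggplot object, or `NULL` (with a message) if the panel is
#'   empty.
#' @export
plot_pair_quadrants <- function(atlas, category, zoom = FALSE) {
  stopifnot(inherits(atlas, "lr_atlas"))
  if (!category %in% lr_categories) {
    rlang::abort(paste0("unknown category `", category, "`"))
  }
  dat <- atlas$pairs |>
    dplyr::filter(.data$category == !!category, .data$plotted)
  if (zoom) dat <- dplyr::filter(dat, .data$quadrant == "high_high")
  if (nrow(dat) == 0L) {
    message("no pairs to plot for category ", category,
            if (zoom) " (zoom)" else "")
    return(invisible(NULL))
  }
  cut10 <- log10(atlas$config$high_cutoff)
  p <- ggplot2::ggplot(dat, ggplot2::aes(
    x = log10(.data$ligand_tpm), y = log10(.data$receptor_tpm)
  )) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$ligand_kind),
                        colour = "grey20", alpha = 0.8) +
    ggplot2::labs(
      x = "log10 ligand TPM (sender tissue)",
      y = "log10 receptor TPM (receiver tissue)",
      title = paste0(gsub("_", " / ", category),
                     if (zoom) " : high/high pairs" else "")
    ) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(legend.position = "none")
  if (!zoom) {
    p <- p +
      ggplot2::geom_hline(yintercept = cut10, linetype = "dashed") +
      ggplot2::geom_vline(xintercept = cut10, linetype = "dashed")
  } else {
    p <- p + ggplot2::geom_text(
      ggplot2::aes(label = paste0(.data$receptor, "←", .data$ligand)),
      size = 2.3, vjust = -0.8)
  }
  p
}

#' @rdname plot_pair_quadrants
#' @param object an `lr_atlas`.
#' @param type which figure: `"top_receptors"`, `"top_autocrine"`,
#'   `"quadrants"` or `"zoom"` (the latter two need `category`).
#' @param ... passed on to the underlying plot function.
#' @export
autoplot.lr_atlas <- function(object, type = c("top_receptors", "top_autocrine",
                                               "quadrants", "zoom"), ...) {
  type <- rlang::arg_match(type)
  switch(type,
    top_receptors = plot_top_genes(object$receptors, object$config$top_n,
                                   "Most highly expressed receptor genes"),
    top_autocrine = plot_top_genes(object$autocrine_ligands, object$config$top_n,
                                   "Most highly expressed ligand genes (receiver tissue)"),
    quadrants = plot_pair_quadrants(object, ...),
    zoom = plot_pair_quadrants(object, zoom = TRUE, ...)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

atlas_summary_list <- function(atlas) {
  qc <- atlas$quadrant_counts
  per_cat <- lapply(lr_categories, function(cat) {
    sub <- qc[qc$category == cat, ]
    list(
      all = as.list(stats::setNames(sub$n_all, sub$quadrant)),
      protein = as.list(stats::setNames(sub$n_protein, sub$quadrant)),
      plotted = as.list(stats::setNames(sub$n_plotted, sub$quadrant))
    )
  })
  names(per_cat) <- lr_categories
  g <- glance(atlas)
  list(
    counts = as.list(g),
    quadrants = per_cat,
    orphans = atlas$orphans$gene,
    missing_ligands = atlas$missing_ligands,
    config = unclass(atlas$config)
  )
}

#' Run the screen end-to-end and write the atlas report
#'
#' Reads the inputs (or accepts in-memory tibbles), runs [lr_screen()] and
#' optionally [overrepresentation()], and writes the atlas to `out_dir`:
#' `receptors.tsv`, one `pairs_<category>.tsv` per category, `orphans.tsv`,
#' `autocrine_ligands.tsv`, `summary.json` (all counts plus the config
#' echo), `enrichment_receptors.tsv` / `enrichment_ligands.tsv` when gene
#' sets are supplied, and figures. Re-running on identical inputs rewrites
#' identical tables.
#'
#' @param receiver,sender TPM tibbles or paths to expression TSVs.
#' @param pairs pair-database tibble or path (default: shipped fixture).
#' @param curation [curation_list()], path to a curation TSV, or `NULL`.
#' @param gene_sets named list of gene sets, path to a GMT file, or `NULL`
#'   to skip enrichment.
#' @param out_dir output directory (created if needed).
#' @param config A [screen_config()].
#' @param figures write figure files too (default `TRUE`).
#' @param fig_format `"png"` or `"svg"`.
#' @return The `lr_atlas`, invisibly.
#' @export
run_screen <- function(receiver, sender, pairs = NULL, curation = NULL,
                       gene_sets = NULL, out_dir, config = screen_config(),
                       figures = TRUE, fig_format = c("png", "svg")) {
  fig_format <- rlang::arg_match(fig_format)
  if (is.character(receiver)) receiver <- read_expression(receiver)
  if (is.character(sender)) sender <- read_expression(sender)
  db <- if (is.null(pairs)) default_pair_db()
        else if (is.character(pairs)) read_pair_db(pairs)
        else validate_pair_db(pairs)
  if (is.character(curation)) curation <- read_curation(curation)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  atlas <- lr_screen(receiver, sender, db = db, curation = curation,
                     config = config)

  flat_receptors <- atlas$receptors |>
    dplyr::mutate(ligand_genes = purrr::map_chr(
      .data$ligands, function(l) paste(l$ligand, collapse = ";"))) |>
    dplyr::select(-"ligands")
  readr::write_tsv(flat_receptors, file.path(out_dir, "receptors.tsv"))
  for (cat in lr_categories) {
    sub <- dplyr::filter(atlas$pairs, .data$category == !!cat)
    readr::write_tsv(sub, file.path(out_dir, paste0("pairs_", cat, ".tsv")),
                     na = "")
  }
  readr::write_tsv(dplyr::select(atlas$orphans, -"ligands"),
                   file.path(out_dir, "orphans.tsv"))
  readr::write_tsv(atlas$autocrine_ligands,
                   file.path(out_dir, "autocrine_ligands.tsv"))
  jsonlite::write_json(atlas_summary_list(atlas),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  if (!is.null(gene_sets)) {
    universe <- atlas$receiver_summary$gene
    enr_rec <- overrepresentation(atlas$receptors$gene, gene_sets, universe)
    readr::write_tsv(enr_rec, file.path(out_dir, "enrichment_receptors.tsv"))
    if (nrow(atlas$autocrine_ligands) > 0) {
      enr_lig <- overrepresentation(atlas$autocrine_ligands$gene, gene_sets,
                                    universe)
      readr::write_tsv(enr_lig, file.path(out_dir, "enrichment_ligands.tsv"))
    }
  }

  if (figures) make_figures(atlas, out_dir, fig_format)
  invisible(atlas)
}

#' Write the atlas figures
#'
#' Top-receptor and autocrine-ligand bar charts, and per-category quadrant
#' scatter plus high/high zoom panels, with deterministic file names
#' (`top_receptors.<ext>`, `pairs_<category>.<ext>`,
#' `pairs_<category>_zoom.<ext>`). Empty panels are skipped with a message.
#'
#' @param atlas an `lr_atlas`.
#' @param out_dir output directory.
#' @param format `"png"` or `"svg"`.
#' @return Character vector of files written, invisibly.
#' @export
make_figures <- function(atlas, out_dir, format = c("png", "svg")) {
  format <- rlang::arg_match(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  save_plot <- function(p, name) {
    if (is.null(p)) return()
    path <- file.path(out_dir, paste0(name, ".", format))
    suppressMessages(ggplot2::ggsave(path, p, width = 7, height = 6, dpi = 150))
    written <<- c(written, path)
  }
  if (nrow(atlas$receptors) > 0) {
    save_plot(autoplot(atlas, "top_receptors"), "top_receptors")
  } else message("no receptors: top-receptor figure skipped")
  if (nrow(atlas$autocrine_ligands) > 0) {
    save_plot(autoplot(atlas, "top_autocrine"), "top_autocrine_ligands")
  } else message("no autocrine ligands: figure skipped")
  for (cat in lr_categories) {
    save_plot(plot_pair_quadrants(atlas, cat), paste0("pairs_", cat))
    save_plot(plot_pair_quadrants(atlas, cat, zoom = TRUE),
              paste0("pairs_", cat, "_zoom"))
  }
  invisible(written)
}
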
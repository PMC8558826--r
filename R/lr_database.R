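#' @keywords internal
lr_categories <- c("growth_factor_wnt", "cytokine_chemokine",
                   "juxtacrine_matricellular", "small_molecule")

#' Validate a ligand-receptor pair database
#'
#' A pair database is a tibble with one row per directed ligand-gene to
#' receptor-gene edge:
#' \describe{
#'   \item{receptor}{receptor gene symbol. Receptor complexes are entered
#'     subunit-by-subunit as independent receptor genes.}
#'   \item{ligand}{ligand gene symbol, or the symbol of a synthesis-enzyme
#'     proxy for a non-protein ligand (e.g. `HDC` for histamine).}
#'   \item{ligand_kind}{`"protein"` or `"synthesis_enzyme_proxy"`.}
#'   \item{molecule}{free-text name of the signaling molecule; required for
#'     proxies, `NA` otherwise.}
#'   \item{categories}{one or more of `growth_factor_wnt`,
#'     `cytokine_chemokine`, `juxtacrine_matricellular`, `small_molecule`,
#'     separated by `";"`. Categories attach to the pair, so one receptor can
#'     appear in several category panels.}
#'   \item{source}{free-text evidence string.}
#' }
#'
#' @param db A data frame as above.
#' @param context label used in error messages (e.g. a file path).
#' @return The validated tibble, with symbols uppercased, invisibly usable
#'   downstream.
#' @export
validate_pair_db <- function(db, context = "pair database") {
  db <- tibble::as_tibble(db)
  required <- c("receptor", "ligand", "ligand_kind", "molecule", "categories", "source")
  missing <- setdiff(required, names(db))
  if (length(missing) > 0L) {
    rlang::abort(paste0(context, ": missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  db$receptor <- normalize_symbols(db$receptor)
  db$ligand <- normalize_symbols(db$ligand)
  db$molecule <- as.character(db$molecule)
  db$source <- as.character(db$source)
  line <- function(i) paste0(context, ", row ", i, ": ")
  for (i in seq_len(nrow(db))) {
    if (is.na(db$receptor[i]) || db$receptor[i] == "") {
      rlang::abort(paste0(line(i), "empty receptor symbol"))
    }
    if (is.na(db$ligand[i]) || db$ligand[i] == "") {
      rlang::abort(paste0(line(i), "empty ligand symbol"))
    }
    if (!db$ligand_kind[i] %in% c("protein", "synthesis_enzyme_proxy")) {
      rlang::abort(paste0(line(i), "unknown ligand_kind `", db$ligand_kind[i], "`"))
    }
    has_mol <- !is.na(db$molecule[i]) && nzchar(db$molecule[i])
    if (db$ligand_kind[i] == "synthesis_enzyme_proxy" && !has_mol) {
      rlang::abort(paste0(line(i), "synthesis-enzyme proxy without a `molecule` name"))
    }
    if (db$ligand_kind[i] == "protein" && has_mol && db$molecule[i] != db$ligand[i]) {
      # molecule is informative only for proxies; tolerate but keep tidy
      db$molecule[i] <- NA_character_
    }
    cats <- strsplit(db$categories[i], ";", fixed = TRUE)[[1]]
    cats <- trimws(cats)
    cats <- cats[nzchar(cats)]
    if (length(cats) == 0L) {
      rlang::abort(paste0(line(i), "empty category set"))
    }
    bad <- setdiff(cats, lr_categories)
    if (length(bad) > 0L) {
      rlang::abort(paste0(line(i), "unknown category token `", bad[1], "`"))
    }
    if ("small_molecule" %in% cats && db$ligand_kind[i] != "synthesis_enzyme_proxy") {
      rlang::abort(paste0(line(i),
        "small_molecule pairs must use a synthesis-enzyme proxy ligand"))
    }
    db$categories[i] <- paste(sort(unique(cats)), collapse = ";")
  }
  key <- paste(db$receptor, db$ligand)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    rlang::abort(paste0(line(i), "duplicate pair (",
                        db$receptor[i], ", ", db$ligand[i], ")"))
  }
  db
}

#' Read a ligand-receptor pair database from TSV
#'
#' @param path TSV with columns `receptor`, `ligand`, `ligand_kind`,
#'   `molecule`, `categories` (`";"`-separated tokens), `source`.
#' @return A validated pair-database tibble (see [validate_pair_db()]).
#' @export
read_pair_db <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("pair database not found: ", path))
  }
  db <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  validate_pair_db(db, context = path)
}

#' Write a pair database to TSV
#'
#' Round-trips with [read_pair_db()]: writing then re-reading a valid
#' database yields an identical pair list.
#'
#' @param db validated pair-database tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_db <- function(db, path) {
  db <- validate_pair_db(db)
  readr::write_tsv(db, path, na = "")
  invisible(path)
}

#' The shipped default pair database
#'
#' A small curated fixture of ligand-receptor pairs assembled from the
#' published bovine morula / endometrium atlas literature: growth factor and
#' WNT pairs (e.g. MDK to ITGB1/SDC4/LRP2, WNT5A to RYK), cytokine and
#' chemokine pairs (e.g. IL18 to CD48, GPI to AMFR), juxtacrine and
#' matricellular pairs (thrombospondins, hedgehogs, ADAMs), and
#' small-molecule receptors with synthesis-enzyme proxy ligands (e.g. HDC
#' for histamine at HRH1). It is a literature-derived curation, not a dump
#' of the full FANTOM5 atlas; supply your own database for genome-scale
#' screens. The ACHE to CHRNB2 entry records acetylcholine as the assigned
#' molecule following the source literature (see the `source` column).
#'
#' @return A validated pair-database tibble.
#' @export
default_pair_db <- function() {
  read_pair_db(system.file("extdata", "bovine_morula_pairs.tsv",
                           package = "lratlas", mustWork = TRUE))
}

#' Read a curation list
#'
#' The curation list makes the manual receptor scrutiny reproducible: it is
#' an explicit, versionable file of receptor symbols to force-include into or
#' exclude from the receptor universe before expression filtering.
#'
#' @param path TSV with columns `gene`, `action` (`include` or `exclude`),
#'   `reason`.
#' @return A list with character vectors `include` and `exclude`.
#' @export
read_curation <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("curation file not found: ", path))
  }
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("gene", "action") %in% names(tbl))) {
    rlang::abort(paste0(path, ": curation file needs `gene` and `action` columns"))
  }
  bad <- setdiff(unique(tbl$action), c("include", "exclude"))
  if (length(bad) > 0L) {
    rlang::abort(paste0(path, ": unknown curation action `", bad[1], "`"))
  }
  curation_list(
    include = normalize_symbols(tbl$gene[tbl$action == "include"]),
    exclude = normalize_symbols(tbl$gene[tbl$action == "exclude"])
  )
}

#' Build a curation list in code
#'
#' @param include receptor symbols forced into the receptor universe.
#' @param exclude receptor symbols removed from it.
#' @return A list of class `curation_list`; `include` and `exclude` must be
#'   disjoint.
#' @export
curation_list <- function(include = character(), exclude = character()) {
  include <- unique(normalize_symbols(include))
  exclude <- unique(normalize_symbols(exclude))
  overlap <- intersect(include, exclude)
  if (length(overlap) > 0L) {
    rlang::abort(paste0("curation include/exclude overlap: ",
                        paste(overlap, collapse = ", ")))
  }
  structure(list(include = include, exclude = exclude), class = "curation_list")
}

#' Apply curation to a receptor symbol set
#'
#' Removes excluded symbols and adds force-included ones. Curation gates
#' membership of the receptor *universe* only; expression filtering happens
#' downstream, so an included gene below the expressed cutoff still drops
#' out of the expressed receptor set.
#'
#' @param receptor_genes character vector of receptor symbols.
#' @param curation a [curation_list()] (or `NULL` for identity).
#' @return The curated symbol set (unique, uppercased, sorted).
#' @export
apply_curation <- function(receptor_genes, curation = NULL) {
  genes <- unique(normalize_symbols(receptor_genes))
  if (is.null(curation)) return(sort(genes))
  stopifnot(inherits(curation, "curation_list"))
  sort(union(setdiff(genes, curation$exclude), curation$include))
}

#' Ligands annotated for a receptor
#'
#' @param db validated pair-database tibble.
#' @param receptor_gene one receptor symbol.
#' @return A tibble of the receptor's ligand rows sorted by ligand symbol
#'   ascending; zero rows for receptors absent from the database (orphans).
#' @export
ligands_of <- function(db, receptor_gene) {
  stopifnot(length(receptor_gene) == 1L)
  db <- tibble::as_tibble(db)
  db |>
    dplyr::filter(.data$receptor == normalize_symbols(receptor_gene)) |>
    dplyr::arrange(.data$ligand) |>
    dplyr::select("ligand", "ligand_kind", "molecule", "categories", "source")
}
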
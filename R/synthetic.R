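#' Configuration for the synthetic crosstalk generator
#'
#' Defines the study conditions the generator emulates: a small number of
#' receiver-tissue replicates (4, as for individually sequenced morulae) and
#' sender-tissue replicates (5 endometrial samples), a heavy-tailed
#' (log-normal) background TPM distribution in which most genes sit below
#' the expressed cutoff, a pair database with multi-ligand and
#' shared-ligand receptors, synthesis-enzyme proxy pairs, orphan receptors,
#' and a planted set of high/high pairs whose true means are separated from
#' the high cutoff by a multiplicative margin.
#'
#' @param n_genes total gene symbols per tissue (default 12000).
#' @param n_receptor_genes receptors in the pair database (default 150).
#' @param ligands_per_receptor integer range, ligand count drawn uniformly
#'   per receptor (default `c(1, 4)`).
#' @param n_orphans expressed receptors absent from the pair database,
#'   supplied via the curation include list (default 15).
#' @param n_proxy_pairs small-molecule pairs whose ligand is a
#'   synthesis-enzyme proxy gene (default 10).
#' @param n_planted_high_high pairs planted with both sides above
#'   `high_cutoff * margin` (default 20).
#' @param margin multiplicative separation of planted (and guarded) true
#'   means from the high cutoff; must exceed 1 (default 2).
#' @param bg_mu,bg_sigma log10-TPM mean and sd of the background
#'   distribution (defaults -0.5 and 1: median 0.32 TPM, ~6% of genes
#'   above 10 TPM).
#' @param n_receiver_samples,n_sender_samples replicate counts (defaults 4
#'   and 5).
#' @param noise_sigma log10-scale sd of the multiplicative replicate noise
#'   (default 0.1).
#' @param share_prob probability that a non-planted ligand slot reuses an
#'   existing ligand gene, creating shared-ligand receptor components
#'   (default 0.2).
#' @param seed RNG seed; the whole simulation is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 12000,
                       n_receptor_genes = 150,
                       ligands_per_receptor = c(1, 4),
                       n_orphans = 15,
                       n_proxy_pairs = 10,
                       n_planted_high_high = 20,
                       margin = 2,
                       bg_mu = -0.5,
                       bg_sigma = 1,
                       n_receiver_samples = 4,
                       n_sender_samples = 5,
                       noise_sigma = 0.1,
                       share_prob = 0.2,
                       seed = 1L) {
  cfg <- list(
    n_genes = n_genes, n_receptor_genes = n_receptor_genes,
    ligands_per_receptor = ligands_per_receptor, n_orphans = n_orphans,
    n_proxy_pairs = n_proxy_pairs,
    n_planted_high_high = n_planted_high_high, margin = margin,
    bg_mu = bg_mu, bg_sigma = bg_sigma,
    n_receiver_samples = n_receiver_samples,
    n_sender_samples = n_sender_samples,
    noise_sigma = noise_sigma, share_prob = share_prob,
    seed = as.integer(seed)
  )
  if (margin <= 1) rlang::abort("`margin` must be > 1")
  counts <- c("n_genes", "n_receptor_genes", "n_orphans", "n_proxy_pairs",
              "n_planted_high_high", "n_receiver_samples", "n_sender_samples")
  for (v in counts) {
    if (cfg[[v]] < 0 || cfg[[v]] != as.integer(cfg[[v]])) {
      rlang::abort(paste0("`", v, "` must be a non-negative integer"))
    }
  }
  if (n_receiver_samples < 1 || n_sender_samples < 1) {
    rlang::abort("each tissue needs at least one replicate")
  }
  if (length(ligands_per_receptor) != 2L ||
      ligands_per_receptor[1] < 1 ||
      ligands_per_receptor[2] < ligands_per_receptor[1]) {
    rlang::abort("`ligands_per_receptor` must be an increasing range >= 1")
  }
  if (n_planted_high_high + n_proxy_pairs > n_receptor_genes) {
    rlang::abort(
      "infeasible config: more planted + proxy pairs than receptor genes")
  }
  structure(cfg, class = "sim_config")
}

# background log-normal draw truncated (by resampling) below `upper`
rlnorm10_below <- function(n, mu, sigma, upper) {
  x <- 10^stats::rnorm(n, mu, sigma)
  while (any(bad <- x >= upper)) {
    x[bad] <- 10^stats::rnorm(sum(bad), mu, sigma)
  }
  x
}

runif_log10 <- function(n, lo, hi) {
  10^stats::runif(n, log10(lo), log10(hi))
}

#' Generate a synthetic cross-tissue screening dataset
#'
#' Draws true per-gene mean TPM on the TPM scale directly (no count layer,
#' no renormalization, so planted margins are exact), then multiplies by
#' per-replicate log-normal noise. Planted high/high pairs get receptor and
#' ligand true means above `high_cutoff * margin`; every gene that could
#' otherwise create a false high/high pair (non-planted receptors, the
#' remaining ligands of planted receptors) is held below
#' `high_cutoff / margin`, so with noise small relative to the margin the
#' screen recovers the planted set exactly. Orphan receptors are omitted
#' from the pair database and force-included via the returned curation
#' list, with true means pinned into the expressed (but not high) band.
#'
#' @param config A [sim_config()].
#' @param screen A [screen_config()]; supplies the cutoffs the planting
#'   margins are anchored to.
#' @return A list with elements `receiver` and `sender` (TPM tibbles),
#'   `pairs` (pair-database tibble), `curation` (a [curation_list()] force
#'   including the orphans), and `truth`: a list with `planted` (tibble of
#'   planted receptor/ligand pairs), `orphans`, `true_receiver_mean`,
#'   `true_sender_mean`, and `expected` (the screen's own output on the
#'   noise-free means: glance counts and quadrant counts).
#' @examples
#' sim <- simulate_crosstalk(sim_config(n_genes = 300, seed = 42))
#' atlas <- lr_screen(sim$receiver, sim$sender, db = sim$pairs,
#'                    curation = sim$curation)
#' setequal(
#'   with(subset(tidy(atlas), quadrant == "high_high"),
#'        paste(receptor, ligand)),
#'   with(sim$truth$planted, paste(receptor, ligand))
#' )
#' @export
simulate_crosstalk <- function(config = sim_config(),
                               screen = screen_config()) {
  stopifnot(inherits(config, "sim_config"), inherits(screen, "screen_config"))
  set.seed(config$seed)
  h <- screen$high_cutoff
  e <- screen$expressed_cutoff
  m <- config$margin

  n_rec <- config$n_receptor_genes
  receptors <- sprintf("RCPT%04d", seq_len(n_rec))
  planted_receptors <- utils::head(receptors, config$n_planted_high_high)
  proxy_receptors <- receptors[seq_len(config$n_proxy_pairs) +
                                 config$n_planted_high_high]
  orphans <- sprintf("ORPH%04d", seq_len(config$n_orphans))

  protein_cats <- setdiff(lr_categories, "small_molecule")
  lig_counter <- 0L
  new_ligand <- function(k) {
    ids <- sprintf("LIG%05d", lig_counter + seq_len(k))
    lig_counter <<- lig_counter + k
    ids
  }

  rows <- list()
  shareable <- character()
  for (r in receptors) {
    if (r %in% proxy_receptors) {
      rows[[r]] <- tibble::tibble(
        receptor = r,
        ligand = sprintf("ENZ%04d", match(r, proxy_receptors)),
        ligand_kind = "synthesis_enzyme_proxy",
        molecule = paste0("molecule_", match(r, proxy_receptors)),
        categories = "small_molecule",
        source = "synthetic"
      )
      next
    }
    n_lig <- sample(seq(config$ligands_per_receptor[1],
                        config$ligands_per_receptor[2]), 1)
    cat_r <- sample(protein_cats, 1)
    if (r %in% planted_receptors) {
      # ligand 1 is the planted partner; extras are dedicated, guarded-low
      ligs <- new_ligand(n_lig)
    } else {
      reuse <- stats::runif(n_lig) < config$share_prob
      pool <- setdiff(shareable, character())
      ligs <- character(n_lig)
      for (i in seq_len(n_lig)) {
        if (reuse[i] && length(setdiff(pool, ligs)) > 0) {
          ligs[i] <- sample(setdiff(pool, ligs), 1)
        } else {
          ligs[i] <- new_ligand(1)
        }
      }
      shareable <- union(shareable, ligs)
    }
    cats <- rep(cat_r, n_lig)
    if (!(r %in% planted_receptors)) {
      # ~10% of pairs carry a second category panel
      second <- stats::runif(n_lig) < 0.1
      cats[second] <- vapply(cats[second], function(cc) {
        paste(sort(c(cc, sample(setdiff(protein_cats, cc), 1))), collapse = ";")
      }, character(1))
    }
    rows[[r]] <- tibble::tibble(
      receptor = r, ligand = ligs, ligand_kind = "protein",
      molecule = NA_character_, categories = cats, source = "synthetic"
    )
  }
  db <- validate_pair_db(dplyr::bind_rows(rows))

  planted <- db |>
    dplyr::filter(.data$receptor %in% planted_receptors) |>
    dplyr::group_by(.data$receptor) |>
    dplyr::slice_min(.data$ligand, n = 1) |>
    dplyr::ungroup() |>
    dplyr::select("receptor", "ligand", "categories")

  all_ligands <- unique(db$ligand)
  guarded_ligands <- db |>
    dplyr::filter(.data$receptor %in% planted_receptors) |>
    dplyr::anti_join(planted, by = c("receptor", "ligand")) |>
    dplyr::pull("ligand")
  free_ligands <- setdiff(all_ligands, c(planted$ligand, guarded_ligands))

  n_named <- n_rec + config$n_orphans + length(all_ligands)
  n_bg <- config$n_genes - n_named
  if (n_bg < 0) {
    rlang::abort("infeasible config: n_genes too small for the pair database")
  }
  bg_genes <- sprintf("BG%06d", seq_len(n_bg))
  genes <- c(receptors, orphans, all_ligands, bg_genes)

  # --- true receiver (receptor-side) means ------------------------------
  rcv <- stats::setNames(numeric(length(genes)), genes)
  rcv[planted_receptors] <- runif_log10(length(planted_receptors), m * h, 10 * m * h)
  other_rec <- setdiff(receptors, planted_receptors)
  rcv[other_rec] <- rlnorm10_below(length(other_rec), config$bg_mu,
                                   config$bg_sigma, h / m)
  rcv[orphans] <- runif_log10(length(orphans), m * e, h / m)
  rcv[all_ligands] <- 10^stats::rnorm(length(all_ligands), config$bg_mu, config$bg_sigma)
  rcv[bg_genes] <- 10^stats::rnorm(n_bg, config$bg_mu, config$bg_sigma)

  # --- true sender (ligand-side) means ----------------------------------
  snd <- stats::setNames(numeric(length(genes)), genes)
  snd[planted$ligand] <- runif_log10(nrow(planted), m * h, 10 * m * h)
  snd[guarded_ligands] <- rlnorm10_below(length(guarded_ligands), config$bg_mu,
                                         config$bg_sigma, h / m)
  snd[free_ligands] <- 10^stats::rnorm(length(free_ligands), config$bg_mu, config$bg_sigma)
  snd[c(other_rec, planted_receptors, orphans)] <-
    10^stats::rnorm(n_rec + config$n_orphans, config$bg_mu, config$bg_sigma)
  snd[bg_genes] <- 10^stats::rnorm(n_bg, config$bg_mu, config$bg_sigma)

  noisy <- function(true_means, n_samp, prefix) {
    out <- tibble::tibble(gene = names(true_means))
    for (i in seq_len(n_samp)) {
      out[[paste0(prefix, i)]] <- unname(
        true_means * 10^stats::rnorm(length(true_means), 0, config$noise_sigma))
    }
    attr(out, "provenance") <- "supplied_tpm"
    out
  }
  receiver <- noisy(rcv, config$n_receiver_samples, "receiver_")
  sender <- noisy(snd, config$n_sender_samples, "sender_")

  curation <- curation_list(include = orphans)

  # expected counts: the screen's own rules applied to the noise-free means
  true_receiver <- tibble::tibble(gene = genes, tpm = unname(rcv))
  true_sender <- tibble::tibble(gene = genes, tpm = unname(snd))
  noise_free <- suppressMessages(lr_screen(
    true_receiver, true_sender, db = db, curation = curation, config = screen))
  truth <- list(
    planted = planted,
    orphans = orphans,
    true_receiver_mean = true_receiver,
    true_sender_mean = true_sender,
    expected = list(
      glance = glance(noise_free),
      quadrant_counts = noise_free$quadrant_counts
    )
  )
  list(receiver = receiver, sender = sender, pairs = db,
       curation = curation, truth = truth, config = config)
}

#' Poisson read counts from a TPM table
#'
#' A secondary, counts-mode generator for exercising the TPM quantifier:
#' draws gene lengths log-uniformly and Poisson read counts with rate
#' proportional to TPM times length times sequencing depth.
#'
#' @param tpm a TPM tibble (`gene` plus sample columns).
#' @param depth expected total reads per sample (default 1e6).
#' @param length_range gene length range in kb, drawn log-uniformly
#'   (default `c(0.5, 10)`).
#' @param seed RNG seed.
#' @return A count tibble (`gene`, `length_kb`, sample columns) suitable
#'   for [compute_tpm()].
#' @export
simulate_counts_from_tpm <- function(tpm, depth = 1e6,
                                     length_range = c(0.5, 10), seed = 1L) {
  set.seed(seed)
  validate_expression(tpm)
  samples <- sample_columns(tpm)
  len <- runif_log10(nrow(tpm), length_range[1], length_range[2])
  out <- tibble::tibble(gene = normalize_symbols(tpm$gene), length_kb = len)
  for (s in samples) {
    lam <- tpm[[s]] * len
    lam <- depth * lam / sum(lam)
    out[[s]] <- stats::rpois(nrow(tpm), lam)
  }
  out
}
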
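# In-code fixtures and independent brute-force oracles. The oracles use
# plain base-R loops and share no code with the package internals.

toy_tpm <- function(genes, ...) {
  vals <- list(...)
  tibble::tibble(gene = genes, !!!vals)
}

toy_db <- function() {
  tibble::tibble(
    receptor = c("ITGB1", "SDC4", "SDC4", "SDC4", "CD48", "CHRNB2"),
    ligand = c("MDK", "MDK", "CXCL10", "CCL5", "IL18", "ACHE"),
    ligand_kind = c(rep("protein", 5), "synthesis_enzyme_proxy"),
    molecule = c(rep(NA_character_, 5), "acetylcholine"),
    categories = c("growth_factor_wnt", "growth_factor_wnt",
                   "cytokine_chemokine", "cytokine_chemokine",
                   "cytokine_chemokine", "small_molecule"),
    source = "test"
  )
}

# random small screen instance: summaries for both tissues plus a pair db
random_instance <- function() {
  n_rec <- sample(3:8, 1)
  receptors <- paste0("R", seq_len(n_rec))
  rows <- do.call(rbind, lapply(receptors, function(r) {
    n_lig <- sample(0:3, 1)
    if (n_lig == 0) return(NULL)
    data.frame(
      receptor = r,
      ligand = paste0("L", sample(1:10, n_lig)),
      ligand_kind = sample(c("protein", "synthesis_enzyme_proxy"), n_lig,
                           replace = TRUE, prob = c(0.8, 0.2)),
      categories = sample(c("growth_factor_wnt", "cytokine_chemokine",
                            "juxtacrine_matricellular",
                            "growth_factor_wnt;cytokine_chemokine"),
                          n_lig, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(rows) || nrow(rows) == 0) return(random_instance())
  rows$molecule <- ifelse(rows$ligand_kind == "synthesis_enzyme_proxy",
                          "mol", NA_character_)
  rows$categories[rows$ligand_kind == "synthesis_enzyme_proxy"] <- "small_molecule"
  rows$source <- "rnd"
  rows <- rows[!duplicated(rows[c("receptor", "ligand")]), ]
  genes <- unique(c(receptors, rows$ligand, paste0("BG", 1:3)))
  rcv <- tibble::tibble(gene = genes,
                        mean_tpm = round(10^runif(length(genes), -1, 2.2), 3),
                        n_samples = 1L)
  snd <- tibble::tibble(gene = sample(genes, max(1, length(genes) - sample(0:2, 1))),
                        mean_tpm = round(10^runif(1, -1, 2.2), 3),
                        n_samples = 1L)
  snd$mean_tpm <- round(10^runif(nrow(snd), -1, 2.2), 3)
  cfg <- screen_config()
  rcv$expressed <- rcv$mean_tpm > cfg$expressed_cutoff
  rcv$high <- rcv$mean_tpm > cfg$high_cutoff
  rcv$very_high <- rcv$mean_tpm > cfg$very_high_cutoff
  snd$expressed <- snd$mean_tpm > cfg$expressed_cutoff
  snd$high <- snd$mean_tpm > cfg$high_cutoff
  snd$very_high <- snd$mean_tpm > cfg$very_high_cutoff
  list(receiver = rcv, sender = snd, db = tibble::as_tibble(rows), config = cfg)
}

# --- oracles ------------------------------------------------------------

oracle_quadrant <- function(r, l, high) {
  if (r > high && l > high) "high_high"
  else if (r > high) "high_low"
  else if (l > high) "low_high"
  else "low_low"
}

oracle_pair_table <- function(receiver, sender, db, cfg) {
  out <- list()
  rec_expressed <- receiver$gene[receiver$mean_tpm > cfg$expressed_cutoff]
  for (i in seq_len(nrow(db))) {
    r <- db$receptor[i]
    if (!(r %in% rec_expressed) || !(r %in% receiver$gene)) next
    rtpm <- receiver$mean_tpm[receiver$gene == r]
    l <- db$ligand[i]
    ltpm <- if (l %in% sender$gene) sender$mean_tpm[sender$gene == l] else 0
    for (cat in strsplit(db$categories[i], ";")[[1]]) {
      out[[length(out) + 1]] <- data.frame(
        category = cat, receptor = r, receptor_tpm = rtpm,
        ligand = l, ligand_kind = db$ligand_kind[i],
        ligand_tpm = ltpm,
        ligand_missing = !(l %in% sender$gene),
        quadrant = oracle_quadrant(rtpm, ltpm, cfg$high_cutoff),
        plotted = rtpm > cfg$expressed_cutoff && ltpm > cfg$ligand_plot_cutoff,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(out)
  out[order(out$category, out$receptor, out$ligand), , drop = FALSE]
}

oracle_count_quadrants <- function(pairs, cat) {
  sub <- pairs[pairs$category == cat, , drop = FALSE]
  sapply(c("high_high", "high_low", "low_high", "low_low"),
         function(q) sum(sub$quadrant == q))
}

oracle_rank_top <- function(summaries, n) {
  ord <- order(-summaries$mean_tpm, summaries$gene)
  summaries$gene[ord][seq_len(min(n, nrow(summaries)))]
}

oracle_orphans <- function(receiver, db, include, cfg) {
  universe <- union(unique(db$receptor), include)
  expressed <- intersect(universe,
                         receiver$gene[receiver$mean_tpm > cfg$expressed_cutoff])
  sort(setdiff(expressed, unique(db$receptor)))
}

# exhaustive hypergeometric upper tail by enumerating all draws
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K) # first K elements are the set
  mean(hits >= k)
}
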
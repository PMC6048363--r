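# Synthetic-data generators with known ground truth. These emulate the
# statistical structure the downstream analyses assume: 96-well screen
# plates with additive row/column artifacts, binomial junction counts
# around planted splicing changes with motif instances embedded upstream
# of repressed exons, and a cross-tissue count matrix with bimodal
# regulator expression anti-correlated with a bimodal exon PSI vector.

.substream <- function(seed, offset) (as.integer(seed) + offset) %% 2147483629L

#' Simulate a 96-well siRNA screen
#'
#' Generates per-well readouts under the additive model that the B-score
#' removes: `value = baseline + row effect + column effect +
#' gene effect (sample wells only) + N(0, noise_sd)`. Column 1 of every
#' plate holds controls (rows 1-4 negative scramble, rows 5-8 positive);
#' the remaining wells carry one siRNA each. Positive controls receive
#' `pos_control_effect` on the cytokine readouts (emulating RELA/CEBPB
#' knockdown suppressing IL-8/IL-6).
#'
#' @param n_genes number of genes; one siRNA (pool) per gene in the
#'   primary-screen layout.
#' @param n_plates number of plates per replicate; defaults to the
#'   minimum that accommodates `n_genes` sample wells.
#' @param replicate_count replicate plates per plate_id (default 3).
#' @param effect_table data.frame with column `gene_id` plus one column
#'   per readout giving the planted effect in units of `noise_sd`
#'   (within-plate SD). Genes absent from the table have effect 0.
#' @param artifact_spec list with `row_sd` and `col_sd`: SDs of the
#'   additive per-row / per-column artifacts (default 0.5 each).
#' @param noise_sd SD of the independent well noise (default 1).
#' @param readouts readout names (default IL8, IL6, p16, p21, BrdU).
#' @param baseline plate-mean raw value per readout (default 100).
#' @param pos_control_effect effect (in noise-SD units) applied to
#'   positive-control wells on `pos_control_readouts` (default -8).
#' @param pos_control_readouts readouts the positive control suppresses.
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `plates` (a [PlateSet-class]) and `truth`
#'   (planted effects, down/up hit gene lists, layout, artifact draws).
#' @export
simulateScreen <- function(n_genes, n_plates = NULL, replicate_count = 3L,
                           effect_table = NULL,
                           artifact_spec = list(row_sd = 0.5, col_sd = 0.5),
                           noise_sd = 1, readouts = c("IL8", "IL6", "p16",
                                                      "p21", "BrdU"),
                           baseline = 100, pos_control_effect = -8,
                           pos_control_readouts = c("IL8", "IL6"),
                           seed = 1L) {
  n_row <- 8L; n_col <- 12L
  sample_per_plate <- n_row * n_col - n_row  # column 1 = controls
  if (is.null(n_plates)) n_plates <- ceiling(n_genes / sample_per_plate)
  if (n_genes > n_plates * sample_per_plate)
    stop(sprintf(
      "capacity error: %d siRNAs exceed %d sample wells (%d plates x %d)",
      n_genes, n_plates * sample_per_plate, n_plates, sample_per_plate))
  set.seed(.substream(seed, 0L))

  genes <- sprintf("gene%05d", seq_len(n_genes))
  eff <- matrix(0, nrow = n_genes, ncol = length(readouts),
                dimnames = list(genes, readouts))
  if (!is.null(effect_table)) {
    effect_table <- as.data.frame(effect_table)
    idx <- match(effect_table$gene_id, genes)
    if (anyNA(idx)) stop("effect_table names genes outside the simulated set")
    for (r in intersect(readouts, names(effect_table)))
      eff[idx, r] <- effect_table[[r]]
  }

  # plate layout: sample wells in columns 2..12. Gene-to-well
  # assignment is randomized across the whole run (as a screening
  # library would be arrayed) so planted effects never align with a
  # plate row or column and alias with the positional artifacts the
  # polish removes.
  layout <- expand.grid(row = seq_len(n_row), col = 2:n_col)
  layout <- layout[order(layout$col, layout$row), ]
  genes_arrayed <- sample(genes)

  all_wells <- vector("list", n_plates * replicate_count)
  k <- 0L
  row_art <- list(); col_art <- list()
  for (p in seq_len(n_plates)) {
    gene_idx <- ((p - 1L) * sample_per_plate + 1L):min(p * sample_per_plate,
                                                       n_genes)
    pg <- genes_arrayed[gene_idx]
    for (rep_i in seq_len(replicate_count)) {
      re <- rnorm(n_row, 0, artifact_spec$row_sd)
      ce <- rnorm(n_col, 0, artifact_spec$col_sd)
      row_art[[sprintf("P%03d_r%d", p, rep_i)]] <- re
      col_art[[sprintf("P%03d_r%d", p, rep_i)]] <- ce

      ctrl <- data.frame(
        plate_id = sprintf("P%03d", p), replicate = rep_i,
        row = seq_len(n_row), col = 1L,
        well_role = rep(c("negative_control", "positive_control"),
                        each = 4L),
        sirna_id = rep(c("si_scramble", "si_positive"), each = 4L),
        gene_id = rep(c("scramble", "positive"), each = 4L),
        stringsAsFactors = FALSE)
      ns <- length(pg)
      samp <- data.frame(
        plate_id = sprintf("P%03d", p), replicate = rep_i,
        row = layout$row[seq_len(ns)], col = layout$col[seq_len(ns)],
        well_role = "sample",
        sirna_id = paste0("si_", pg), gene_id = pg,
        stringsAsFactors = FALSE)
      empty_n <- sample_per_plate - ns
      if (empty_n > 0) {
        idx2 <- (ns + 1L):sample_per_plate
        emp <- data.frame(
          plate_id = sprintf("P%03d", p), replicate = rep_i,
          row = layout$row[idx2], col = layout$col[idx2],
          well_role = "empty", sirna_id = "", gene_id = "",
          stringsAsFactors = FALSE)
      } else emp <- NULL
      wl <- rbind(ctrl, samp, emp)
      for (r in readouts) {
        g_eff <- numeric(nrow(wl))
        is_s <- wl$well_role == "sample"
        g_eff[is_s] <- eff[wl$gene_id[is_s], r]
        if (r %in% pos_control_readouts)
          g_eff[wl$well_role == "positive_control"] <- pos_control_effect
        wl[[r]] <- baseline + re[wl$row] + ce[wl$col] +
          g_eff * noise_sd + rnorm(nrow(wl), 0, noise_sd)
      }
      k <- k + 1L
      all_wells[[k]] <- wl
    }
  }
  wells <- do.call(rbind, all_wells)
  down <- genes[apply(eff < 0, 1L, any)]
  up <- genes[apply(eff > 0, 1L, any)]
  list(
    plates = PlateSet(wells, readouts = readouts),
    truth = list(effects = eff, down_hits = down, up_hits = up,
                 layout = layout, arrayed_order = genes_arrayed,
                 row_artifacts = row_art,
                 col_artifacts = col_art, noise_sd = noise_sd,
                 baseline = baseline))
}

.sampleMotifWord <- function(motif) {
  p <- motifProbs(motif)
  paste(vapply(seq_len(ncol(p)), function(j)
    sample(rownames(p), 1L, prob = p[, j]), character(1)), collapse = "")
}

.randomSeq <- function(n, comp = rep(0.25, 4)) {
  paste(sample(.DNA_ALPHABET, n, replace = TRUE, prob = comp), collapse = "")
}

#' Simulate cassette-exon splicing data
#'
#' Generates an event table, per-sample junction counts, flanking
#' sequences and ground truth for a knockdown-vs-control contrast.
#' Each cassette exon has two inclusion junctions and one skipping
#' junction, each drawn `Binomial(coverage, PSI)` (skipping:
#' `1 - PSI`). Repressed events gain `delta_psi` inclusion upon
#' knockdown (the direction expected when a repressor is depleted),
#' enhanced events lose it, unchanged events keep their baseline PSI.
#' Repressed events carry at least one embedded motif instance inside
#' `placement_window` (offsets relative to the 3' splice site, negative
#' = intronic); other events carry background-only sequence.
#'
#' @param n_events number of cassette exon events.
#' @param class_proportions named numeric vector over
#'   `repressed/enhanced/unchanged` (normalized internally).
#' @param coverage binomial size per junction (default 100).
#' @param delta_psi planted |PSI| change (default 0.3).
#' @param n_replicates replicates per condition (default 3).
#' @param flank_len intronic flank length emitted per side (default 300).
#' @param motif a [MotifMatrix-class] (or literal string) planted in
#'   repressed events; default the shipped synthetic CU-rich matrix.
#' @param placement_window integer length-2, offsets relative to the 3'
#'   splice site within which motif instances are placed
#'   (default `c(-60, -20)`, half-open).
#' @param exon_len length of the alternative exon (default 120).
#' @param background_comp background base composition for the flanks.
#' @param seed integer seed.
#' @return list with `events`, `junction_counts` (long data.frame),
#'   `sequences` (named character; `<event_id>|upstream_intron`,
#'   `|exon`, `|downstream_intron`, transcript orientation),
#'   `regions` (map from sequence records to genomic intervals) and
#'   `truth` (true PSI per condition, class, motif placements).
#' @export
simulateSplicing <- function(n_events,
                             class_proportions = c(repressed = 0.15,
                                                   enhanced = 0.1,
                                                   unchanged = 0.75),
                             coverage = 100, delta_psi = 0.3,
                             n_replicates = 3L, flank_len = 300L,
                             motif = NULL,
                             placement_window = c(-60L, -20L),
                             exon_len = 120L,
                             background_comp = rep(0.25, 4), seed = 1L) {
  set.seed(.substream(seed, 1000L))
  if (is.null(motif)) motif <- .defaultCuRichMotif()
  if (is.character(motif)) {
    word <- chartr("U", "T", toupper(motif))
    motif_len <- nchar(word)
    literal <- TRUE
  } else {
    stopifnot(is(motif, "MotifMatrix"))
    motif_len <- motifWidth(motif)
    literal <- FALSE
  }
  if (motif_len > diff(placement_window))
    stop("parameter error: motif longer than the placement window")
  if (placement_window[1L] < -flank_len || placement_window[2L] > 0L)
    stop("parameter error: placement window must lie within the upstream flank")

  cp <- class_proportions[c("repressed", "enhanced", "unchanged")]
  cp[is.na(cp)] <- 0
  cp <- cp / sum(cp)
  names(cp) <- c("repressed", "enhanced", "unchanged")
  lo0 <- 0.05
  if (sum(cp[c("repressed", "enhanced")]) > 0 &&
      1 - delta_psi - 2 * lo0 <= 0)
    stop("parameter error: true PSI +/- delta_psi must stay within [0,1]")
  classes <- sample(names(cp), n_events, replace = TRUE, prob = cp)
  ev_id <- sprintf("ev%05d", seq_len(n_events))

  psi_ctrl <- numeric(n_events)
  psi_kd <- numeric(n_events)
  lo <- 0.05
  for (i in seq_len(n_events)) {
    if (classes[i] == "repressed") {
      if (1 - delta_psi - 2 * lo <= 0)
        stop("parameter error: true PSI +/- delta_psi must stay within [0,1]")
      psi_ctrl[i] <- runif(1, lo, 1 - delta_psi - lo)
      psi_kd[i] <- psi_ctrl[i] + delta_psi
    } else if (classes[i] == "enhanced") {
      psi_ctrl[i] <- runif(1, delta_psi + lo, 1 - lo)
      psi_kd[i] <- psi_ctrl[i] - delta_psi
    } else {
      psi_ctrl[i] <- runif(1, lo, 1 - lo)
      psi_kd[i] <- psi_ctrl[i]
    }
  }

  # genomic scaffolding: one event per locus, alternating strand
  strand <- sample(c("+", "-"), n_events, replace = TRUE)
  gap <- 10000L
  alt_start <- seq_len(n_events) * gap
  events <- data.frame(
    event_id = ev_id, event_type = "SE", chrom = "chrS",
    strand = strand, gene_id = paste0("g_", ev_id),
    up_start = alt_start - flank_len - 200L,
    up_end = alt_start - flank_len,
    alt_start = alt_start, alt_end = alt_start + exon_len,
    down_start = alt_start + exon_len + flank_len,
    down_end = alt_start + exon_len + flank_len + 200L,
    score = 0, stringsAsFactors = FALSE)

  # junction counts
  cond <- c("control", "knockdown")
  jc <- expand.grid(event_id = ev_id, condition = cond,
                    replicate = seq_len(n_replicates),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  jc$sample_id <- paste0(jc$condition, "_r", jc$replicate)
  psi_true <- ifelse(jc$condition == "control",
                     psi_ctrl[match(jc$event_id, ev_id)],
                     psi_kd[match(jc$event_id, ev_id)])
  n <- nrow(jc)
  jc$inc1 <- rbinom(n, coverage, psi_true)
  jc$inc2 <- rbinom(n, coverage, psi_true)
  jc$skip <- rbinom(n, coverage, 1 - psi_true)
  jc <- jc[, c("event_id", "sample_id", "condition", "replicate",
               "inc1", "inc2", "skip")]

  # sequences (transcript orientation) + motif placement
  seqs <- character(0)
  regions <- list()
  placements <- list()
  for (i in seq_len(n_events)) {
    up <- .randomSeq(flank_len, background_comp)
    ex <- .randomSeq(exon_len, background_comp)
    dn <- .randomSeq(flank_len, background_comp)
    if (classes[i] == "repressed") {
      word <- if (literal) word else .sampleMotifWord(motif)
      off <- sample(seq(placement_window[1L],
                        placement_window[2L] - motif_len), 1L)
      pos <- flank_len + off  # 0-based within the upstream flank
      substr(up, pos + 1L, pos + motif_len) <- word
      placements[[ev_id[i]]] <- c(offset = off, length = motif_len)
    }
    nm <- paste0(ev_id[i], c("|upstream_intron", "|exon",
                             "|downstream_intron"))
    seqs[nm] <- c(up, ex, dn)
    # genomic interval of each record; minus-strand records are the
    # reverse complement of the genomic interval (transcript sense)
    if (strand[i] == "+") {
      g <- rbind(c(events$alt_start[i] - flank_len, events$alt_start[i]),
                 c(events$alt_start[i], events$alt_end[i]),
                 c(events$alt_end[i], events$alt_end[i] + flank_len))
    } else {
      g <- rbind(c(events$alt_end[i], events$alt_end[i] + flank_len),
                 c(events$alt_start[i], events$alt_end[i]),
                 c(events$alt_start[i] - flank_len, events$alt_start[i]))
    }
    regions[[i]] <- data.frame(
      sequence_id = nm, event_id = ev_id[i],
      region = c("upstream_intron", "exon", "downstream_intron"),
      chrom = "chrS", g_start = g[, 1L], g_end = g[, 2L],
      strand = strand[i], stringsAsFactors = FALSE)
  }
  truth <- list(
    class = setNames(classes, ev_id),
    psi_control = setNames(psi_ctrl, ev_id),
    psi_knockdown = setNames(psi_kd, ev_id),
    motif_placements = placements, coverage = coverage,
    delta_psi = delta_psi)
  list(events = events, junction_counts = jc, sequences = seqs,
       regions = do.call(rbind, regions), truth = truth)
}

#' Simulate a cross-tissue expression matrix with a bimodal regulator
#'
#' Samples fall into two latent states: regulator-high / exon-included
#' (low skipping) and regulator-low / exon-skipped. The regulator's
#' expression is bimodal across samples and anti-correlated with the
#' returned exon PSI vector; members of a planted gene set are
#' up-shifted in the high-skipping state, so they rank at the top of a
#' high-vs-low-skipping differential comparison.
#'
#' @param n_genes number of background genes (default 2000).
#' @param n_samples number of samples (default 300).
#' @param regulator_modes list with `low` and `high`, each `c(mean, sd)`
#'   on the log2 expression scale of the regulator.
#' @param psi_modes list with `included` and `skipped`, each
#'   `c(mean, sd)` of the PSI (values truncated to [0,1]).
#' @param enriched_set_size members of the planted gene set (default 50).
#' @param enrich_lfc log2 up-shift of planted genes in high-skipping
#'   samples (default 1).
#' @param lib_size mean library size (default 1e6); must be positive.
#' @param regulator_name row name used for the regulator (default
#'   `"PTBP1"`).
#' @param seed integer seed.
#' @return list with `counts` (gene x sample), `psi` (named numeric per
#'   sample), and `truth` (`state` per sample, `enriched_set`,
#'   regulator name).
#' @export
simulateTissueMatrix <- function(n_genes = 2000L, n_samples = 300L,
                                 regulator_modes = list(low = c(5, 0.5),
                                                        high = c(9, 0.5)),
                                 psi_modes = list(included = c(0.8, 0.07),
                                                  skipped = c(0.2, 0.07)),
                                 enriched_set_size = 50L, enrich_lfc = 1,
                                 lib_size = 1e6,
                                 regulator_name = "PTBP1", seed = 1L) {
  if (lib_size <= 0) stop("parameter error: library size must be positive")
  set.seed(.substream(seed, 2000L))
  state <- sample(c("regulator_high", "regulator_low"), n_samples,
                  replace = TRUE)
  hi <- state == "regulator_high"
  genes <- sprintf("g%05d", seq_len(n_genes))
  enriched <- if (enriched_set_size > 0)
    sample(genes, enriched_set_size) else character(0)

  base_log2 <- rnorm(n_genes, 6, 1.5)
  log2_expr <- matrix(rep(base_log2, n_samples), nrow = n_genes)
  # regulator-high samples skip the exon; the planted set is up there
  log2_expr[genes %in% enriched, hi] <-
    log2_expr[genes %in% enriched, hi] + enrich_lfc
  log2_expr <- log2_expr + rnorm(length(log2_expr), 0, 0.4)

  reg <- numeric(n_samples)
  reg[hi] <- rnorm(sum(hi), regulator_modes$high[1L],
                   regulator_modes$high[2L])
  reg[!hi] <- rnorm(sum(!hi), regulator_modes$low[1L],
                    regulator_modes$low[2L])
  log2_expr <- rbind(reg, log2_expr)
  rownames(log2_expr) <- c(regulator_name, genes)

  rel <- 2^log2_expr
  rel <- sweep(rel, 2L, colSums(rel), "/")
  counts <- matrix(
    rbinom(length(rel), size = as.integer(lib_size), prob = rel),
    nrow = nrow(rel), dimnames = dimnames(rel))
  colnames(counts) <- sprintf("s%04d", seq_len(n_samples))

  psi <- numeric(n_samples)
  psi[hi] <- rnorm(sum(hi), psi_modes$skipped[1L], psi_modes$skipped[2L])
  psi[!hi] <- rnorm(sum(!hi), psi_modes$included[1L],
                    psi_modes$included[2L])
  psi <- pmin(pmax(psi, 0), 1)
  names(psi) <- colnames(counts)

  list(counts = counts, psi = psi,
       truth = list(state = setNames(state, colnames(counts)),
                    enriched_set = enriched,
                    regulator = regulator_name))
}

# shipped synthetic CU-rich motif (stand-in, not a published matrix)
.defaultCuRichMotif <- function() {
  path <- system.file("extdata", "cu_rich_motif_synthetic.tsv",
                      package = "sasptools")
  if (nzchar(path)) return(readMotifMatrix(path))
  # fallback during in-source testing
  m <- matrix(0.02, 4, 5, dimnames = list(.DNA_ALPHABET, NULL))
  m["T", ] <- c(0.9, 0.05, 0.9, 0.9, 0.05)
  m["C", ] <- c(0.04, 0.88, 0.04, 0.04, 0.88)
  motifMatrix(m)
}
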
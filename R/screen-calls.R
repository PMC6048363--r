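# Hit calling for the primary and secondary screens and K-means triage
# of SASP-repressing siRNAs into phenotype clusters.

#' Call primary-screen hits
#'
#' A siRNA (pool) is a down-hit when its B-score is at or below
#' `down_cutoff` in at least `min_replicates` of `n_replicates`
#' replicates for BOTH readouts; up-hits analogously at or above
#' `up_cutoff`. The symmetric default cutoffs (-2, +2) correspond to
#' the +/- 2 SD scramble-control lines; `as_printed = TRUE` selects the
#' literal published wording of the rule (down < -2, up > 3) instead.
#'
#' @param bscores long data.frame as returned by [bScore()] (stacked
#'   over readouts/replicates); columns `sirna_id, gene_id, replicate,
#'   readout, b`. Control and empty wells are ignored.
#' @param readouts the two cytokine readouts (default `c("IL8","IL6")`).
#' @param down_cutoff,up_cutoff B-score cutoffs (defaults -2, +2).
#' @param min_replicates consensus requirement (default 2).
#' @param n_replicates expected replicates (default 3).
#' @param as_printed use the literal rule reading (down < -2, up > 3).
#' @return data.frame: `sirna_id, gene_id, direction`
#'   (`down`/`up`/`none`) and per-readout replicate pass counts
#'   (`n_down_<readout>`, `n_up_<readout>`), plus `rule_version`.
#' @export
callPrimaryHits <- function(bscores, readouts = c("IL8", "IL6"),
                            down_cutoff = -2, up_cutoff = 2,
                            min_replicates = 2L, n_replicates = 3L,
                            as_printed = FALSE) {
  b <- bscores
  if ("well_role" %in% names(b))
    b <- b[b$well_role == "sample", , drop = FALSE]
  b <- b[b$readout %in% readouts, , drop = FALSE]
  rule <- if (as_printed) "as_printed(b< -2, b>3)" else
    sprintf("symmetric(b<=%g, b>=%g)", down_cutoff, up_cutoff)
  if (as_printed) { down_cutoff <- -2; up_cutoff <- 3 }
  down_fun <- if (as_printed) function(x) x < down_cutoff else
    function(x) x <= down_cutoff
  up_fun <- if (as_printed) function(x) x > up_cutoff else
    function(x) x >= up_cutoff

  sirnas <- unique(b[, c("sirna_id", "gene_id")])
  res <- sirnas
  for (r in readouts) {
    br <- b[b$readout == r, ]
    cover <- table(br$sirna_id)
    short <- setdiff(sirnas$sirna_id, names(cover)[cover >= min_replicates])
    if (length(short) > 0)
      stop(sprintf(
        "coverage error: readout %s missing for siRNA(s) %s", r,
        paste(head(short, 5L), collapse = ", ")))
    nd <- tapply(down_fun(br$b), br$sirna_id, sum)
    nu <- tapply(up_fun(br$b), br$sirna_id, sum)
    res[[paste0("n_down_", r)]] <- as.integer(nd[res$sirna_id])
    res[[paste0("n_up_", r)]] <- as.integer(nu[res$sirna_id])
  }
  down_all <- Reduce(`&`, lapply(readouts, function(r)
    res[[paste0("n_down_", r)]] >= min_replicates))
  up_all <- Reduce(`&`, lapply(readouts, function(r)
    res[[paste0("n_up_", r)]] >= min_replicates))
  res$direction <- ifelse(down_all, "down", ifelse(up_all, "up", "none"))
  res$rule_version <- rule
  rownames(res) <- NULL
  res[order(res$sirna_id), ]
}

# pooled-variance (Student) two-sample t; Welch optional
.twoSampleT <- function(m1, v1, n1, m2, v2, n2, var_equal = TRUE) {
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Secondary-screen validation
#'
#' For every siRNA and readout the replicate NPI values are compared
#' with all scramble NPI values by an unpaired two-sided Student
#' (pooled-variance) t test. A siRNA qualifies on a readout when its
#' mean NPI is below `npi_cutoff` AND p <= `alpha`; a gene passes when
#' at least `min_sirnas` of its siRNAs qualify on both readouts.
#' P values are reported raw, as in the published rule; set
#' `adjust = "BH"` for Benjamini-Hochberg-adjusted qualification.
#'
#' @param npi_table long data.frame: `sirna_id, gene_id, readout,
#'   replicate, npi` (sample siRNAs only).
#' @param scramble_values named list: per readout, the vector of all
#'   scramble NPI values.
#' @param npi_cutoff NPI threshold (default 0.8, applied to the
#'   replicate mean).
#' @param alpha p-value threshold (default 0.05).
#' @param min_sirnas sibling siRNAs required per gene (default 2).
#' @param var_equal pooled-variance Student t (default) or Welch.
#' @param adjust `"none"` (default, as published) or `"BH"`.
#' @return list with `sirna` (per siRNA x readout: `npi_mean, p,
#'   qualify`) and `gene` (per gene: `n_qualifying, gene_pass`).
#' @export
secondaryValidation <- function(npi_table, scramble_values,
                                npi_cutoff = 0.8, alpha = 0.05,
                                min_sirnas = 2L, var_equal = TRUE,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  readouts <- unique(npi_table$readout)
  miss <- setdiff(readouts, names(scramble_values))
  if (length(miss) > 0)
    stop(sprintf("missing scramble values for readout(s) %s",
                 paste(miss, collapse = ", ")))
  rows <- list()
  for (r in readouts) {
    scr <- scramble_values[[r]]
    if (length(scr) < 2L)
      stop(sprintf("need >= 2 scramble values for readout %s", r))
    sm <- mean(scr); sv <- var(scr); sn <- length(scr)
    nt <- npi_table[npi_table$readout == r, ]
    sp <- split(nt, nt$sirna_id)
    m <- vapply(sp, function(d) mean(d$npi), numeric(1))
    v <- vapply(sp, function(d) var(d$npi), numeric(1))
    n <- vapply(sp, nrow, integer(1))
    tt <- .twoSampleT(m, v, n, sm, sv, sn, var_equal = var_equal)
    if (any(!is.finite(tt$t)))
      stop("degenerate variance: zero pooled variance in a t test")
    rows[[r]] <- data.frame(
      sirna_id = names(sp),
      gene_id = vapply(sp, function(d) d$gene_id[1L], character(1)),
      readout = r, npi_mean = m, t = tt$t, p = tt$p,
      stringsAsFactors = FALSE)
  }
  sirna <- do.call(rbind, rows)
  rownames(sirna) <- NULL
  p_use <- if (adjust == "BH") bhFdr(sirna$p) else sirna$p
  sirna$qualify <- sirna$npi_mean < npi_cutoff & p_use <= alpha

  qual_both <- tapply(sirna$qualify, sirna$sirna_id, all)
  sirna_gene <- tapply(sirna$gene_id, sirna$sirna_id, `[`, 1L)
  n_qual <- tapply(unname(qual_both), unname(sirna_gene), sum)
  gene <- data.frame(gene_id = names(n_qual),
                     n_qualifying = as.integer(n_qual),
                     gene_pass = as.integer(n_qual) >= min_sirnas,
                     stringsAsFactors = FALSE)
  rownames(gene) <- NULL
  list(sirna = sirna[order(sirna$sirna_id, sirna$readout), ],
       gene = gene[order(gene$gene_id), ])
}

# k-means++ seeding (Arthur & Vassilvitskii)
.kmeansPlusPlusInit <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) idx <- sample.int(n, 1L)
    else idx <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' K-means clustering of phenotype profiles
#'
#' Lloyd's algorithm with k-means++ initialization, `n_init` restarts,
#' keeping the solution with the smallest within-cluster sum of
#' squares. Euclidean distance on the raw B-score feature columns;
#' deterministic under a fixed seed.
#'
#' @param profiles data.frame with `sirna_id` and numeric feature
#'   columns (per-replicate B-scores of p16, p21, BrdU, optionally the
#'   cytokines), or a plain numeric matrix.
#' @param k number of clusters (default 4).
#' @param n_init number of restarts (default 25).
#' @param seed integer seed.
#' @param iter_max Lloyd iterations per restart (default 100).
#' @return list with `cluster` (assignments, named when `sirna_id`
#'   present), `centers`, `tot_withinss`, `features`.
#' @export
kmeansCluster <- function(profiles, k = 4L, n_init = 25L, seed = 1L,
                          iter_max = 100L) {
  if (is.data.frame(profiles)) {
    feat <- names(profiles)[vapply(profiles, is.numeric, logical(1))]
    x <- as.matrix(profiles[, feat, drop = FALSE])
    if ("sirna_id" %in% names(profiles)) rownames(x) <- profiles$sirna_id
  } else {
    x <- as.matrix(profiles)
    feat <- colnames(x)
  }
  if (k > nrow(x))
    stop(sprintf("parameter error: k = %d exceeds %d profiles", k, nrow(x)))
  if (any(!is.finite(x))) stop("features must be finite")
  set.seed(.substream(seed, 3000L))
  best <- NULL
  for (i in seq_len(n_init)) {
    init <- .kmeansPlusPlusInit(x, k)
    fit <- suppressWarnings(
      kmeans(x, centers = init, iter.max = iter_max, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  list(cluster = setNames(best$cluster, rownames(x)),
       centers = best$centers, tot_withinss = best$tot.withinss,
       features = feat)
}

#' Label phenotype clusters
#'
#' Assigns each cluster a senescence-phenotype role from its centroid's
#' deviation from a reference (scramble + induced) profile, aggregated
#' per readout over replicate feature columns:
#' `arrest_reverted` when BrdU rises by at least `reversion_margin`
#' B-score units AND p16 or p21 falls by at least the margin;
#' `arrest_exacerbated` when p21 rises by at least the margin;
#' `sasp_only` when all three deviations stay inside the margin;
#' otherwise `other`. Ties resolve by precedence
#' reverted > exacerbated > sasp_only (recorded in the output).
#'
#' @param centers centroid matrix from [kmeansCluster()]; feature
#'   columns must contain the readout name (`p16`, `p21`, `BrdU`).
#' @param reference named numeric reference vector (same convention) or
#'   a single 0 (default) for already-centered B-scores.
#' @param reversion_margin margin in B-score units (default 2).
#' @return data.frame: `cluster_id, brdu_dev, p16_dev, p21_dev,
#'   cluster_role, precedence`.
#' @export
labelClusters <- function(centers, reference = 0, reversion_margin = 2) {
  agg <- function(v, nm) {
    idx <- grepl(nm, names(v), ignore.case = TRUE)
    if (!any(idx)) stop(sprintf("no feature column matches '%s'", nm))
    mean(v[idx])
  }
  ref <- if (length(reference) == 1L)
    c(BrdU = reference, p16 = reference, p21 = reference)
  else c(BrdU = agg(reference, "BrdU"), p16 = agg(reference, "p16"),
         p21 = agg(reference, "p21"))
  out <- lapply(seq_len(nrow(centers)), function(i) {
    v <- setNames(as.numeric(centers[i, ]), colnames(centers))
    dev <- c(BrdU = agg(v, "BrdU") - ref["BrdU"],
             p16 = agg(v, "p16") - ref["p16"],
             p21 = agg(v, "p21") - ref["p21"])
    names(dev) <- c("BrdU", "p16", "p21")
    reverted <- dev["BrdU"] >= reversion_margin &&
      (dev["p16"] <= -reversion_margin || dev["p21"] <= -reversion_margin)
    exacerbated <- dev["p21"] >= reversion_margin
    sasp_only <- all(abs(dev) < reversion_margin)
    role <- if (reverted) "arrest_reverted"
    else if (exacerbated) "arrest_exacerbated"
    else if (sasp_only) "sasp_only"
    else "other"
    data.frame(cluster_id = i, brdu_dev = dev[["BrdU"]],
               p16_dev = dev[["p16"]], p21_dev = dev[["p21"]],
               cluster_role = role,
               precedence = "reverted>exacerbated>sasp_only",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
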
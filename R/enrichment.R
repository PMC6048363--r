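# Benjamini-Hochberg FDR utility and preranked gene-set enrichment
# (running-sum ES, gene-label permutation null, NES, nominal p and
# sign-stratified FDR q).

#' Benjamini-Hochberg FDR
#'
#' Step-up BH adjustment with monotonicity enforcement; a thin
#' domain-validating wrapper around the standard adjustment.
#'
#' @param pvals numeric p-values, all in (0, 1].
#' @return Adjusted q-values in (0, 1], in input order.
#' @export
bhFdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("domain error: p-values must lie in (0, 1]")
  p.adjust(pvals, method = "BH")
}

# running-sum enrichment score; scores must be sorted descending
.gseaES <- function(scores, hit_idx, weight_exponent = 1,
                    return_path = FALSE) {
  n <- length(scores)
  n_hit <- length(hit_idx)
  w <- abs(scores[hit_idx])^weight_exponent
  nr <- sum(w)
  inc <- numeric(n)
  if (nr > 0) inc[hit_idx] <- w / nr else inc[hit_idx] <- 1 / n_hit
  miss <- rep(1 / (n - n_hit), n)
  miss[hit_idx] <- 0
  path <- cumsum(inc - miss)
  i <- which.max(abs(path))
  if (return_path) list(es = path[i], peak = i, path = path)
  else path[i]
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov running-sum GSEA on a preranked
#' list. Walking the list from the top, set members increment the
#' running sum proportionally to `|score|^weight_exponent` (normalized
#' over the set's members) and non-members decrement it by
#' `1/(N - set size)`; the enrichment score ES is the signed maximum
#' deviation. The null is built from gene-label permutations (random
#' sets of equal size); `NES = ES / mean(|null ES| of the matching
#' sign)`, the nominal p is the fraction of same-sign null ES at least
#' as extreme, and the FDR q follows the standard sign-stratified
#' comparison of the observed and pooled null NES across all tested
#' sets.
#'
#' @param ranked data.frame with columns `gene` and `score`, or a
#'   named numeric vector of scores. Ties are broken by gene id
#'   (stable, recorded by the sort).
#' @param gene_sets named list of character vectors.
#' @param weight_exponent hit-weight exponent (default 1, the classic
#'   weighted statistic; 0 gives the unweighted KS form).
#' @param n_perm permutations (default 1000, minimum 100).
#' @param seed integer seed; fixed seed gives identical results.
#' @param min_size sets with fewer overlapping genes are skipped
#'   (default 2).
#' @return data.frame: `set, size, es, nes, p_nominal, fdr_q,
#'   leading_edge_size`, with a `leading_edge` attribute (named list of
#'   gene vectors).
#' @export
gseaPreranked <- function(ranked, gene_sets, weight_exponent = 1,
                          n_perm = 1000L, seed = 1L, min_size = 2L) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (is.data.frame(ranked)) {
    scores <- ranked$score
    genes <- as.character(ranked$gene)
  } else {
    scores <- as.numeric(ranked)
    genes <- names(ranked)
  }
  if (anyDuplicated(genes)) stop("ranked list gene ids must be unique")
  o <- order(-scores, genes)
  scores <- scores[o]; genes <- genes[o]
  n <- length(genes)
  set.seed(.substream(seed, 4000L))

  keep <- vapply(gene_sets, function(s) {
    k <- sum(s %in% genes)
    k >= min_size && k < n
  }, logical(1))
  if (any(vapply(gene_sets, function(s) all(genes %in% s), logical(1))))
    stop("degenerate set: a gene set covers the whole ranked list")
  gene_sets <- gene_sets[keep]
  if (length(gene_sets) == 0) stop("no testable gene sets")

  hits <- lapply(gene_sets, function(s) which(genes %in% s))
  sizes <- vapply(hits, length, integer(1))

  es <- numeric(length(hits))
  le <- vector("list", length(hits))
  for (i in seq_along(hits)) {
    r <- .gseaES(scores, hits[[i]], weight_exponent, return_path = TRUE)
    es[i] <- r$es
    le[[i]] <- if (r$es >= 0) genes[intersect(hits[[i]], seq_len(r$peak))]
    else genes[intersect(hits[[i]], r$peak:n)]
  }
  names(le) <- names(gene_sets)

  # permutation null per distinct set size
  null_es <- matrix(NA_real_, nrow = n_perm, ncol = length(hits))
  for (us in unique(sizes)) {
    cols <- which(sizes == us)
    m <- matrix(NA_real_, n_perm, length(cols))
    for (b in seq_len(n_perm)) {
      idx <- sort(sample.int(n, us))
      e <- .gseaES(scores, idx, weight_exponent)
      m[b, ] <- e
    }
    null_es[, cols] <- m
  }

  nes <- numeric(length(es))
  p_nom <- numeric(length(es))
  null_nes <- matrix(NA_real_, n_perm, length(es))
  for (i in seq_along(es)) {
    nv <- null_es[, i]
    pos_mean <- mean(nv[nv >= 0])
    neg_mean <- mean(abs(nv[nv < 0]))
    if (es[i] >= 0) {
      same <- nv[nv >= 0]
      p_nom[i] <- (sum(same >= es[i]) + 1) / (length(same) + 1)
      nes[i] <- es[i] / pos_mean
    } else {
      same <- nv[nv < 0]
      p_nom[i] <- (sum(same <= es[i]) + 1) / (length(same) + 1)
      nes[i] <- es[i] / neg_mean
    }
    null_nes[, i] <- ifelse(nv >= 0, nv / pos_mean, nv / neg_mean)
  }

  # sign-stratified FDR: fraction of pooled null NES at least as
  # extreme, over the fraction of observed NES at least as extreme
  fdr <- numeric(length(nes))
  pooled <- as.vector(null_nes)
  for (i in seq_along(nes)) {
    if (nes[i] >= 0) {
      denom_null <- sum(pooled >= 0)
      num <- sum(pooled >= nes[i]) / max(denom_null, 1L)
      obs <- sum(nes >= nes[i]) / max(sum(nes >= 0), 1L)
    } else {
      denom_null <- sum(pooled < 0)
      num <- sum(pooled <= nes[i]) / max(denom_null, 1L)
      obs <- sum(nes <= nes[i]) / max(sum(nes < 0), 1L)
    }
    fdr[i] <- min(1, num / max(obs, .Machine$double.eps))
  }

  res <- data.frame(set = names(gene_sets), size = sizes, es = es,
                    nes = nes, p_nominal = p_nom, fdr_q = pmax(fdr,
                                                               1e-16),
                    leading_edge_size = vapply(le, length, integer(1)),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res <- res[order(res$p_nominal, res$set), ]
  attr(res, "leading_edge") <- le
  res
}
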
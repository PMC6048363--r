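# Motif scanning with exact p-values and the RNA map: positional motif
# density per exon-response group with moving-window Fisher enrichment
# against the unregulated group.

# exact distribution of the log-odds score of a random word under the
# background model. For widths <= `exact_max_width` the full set of
# achievable score sums is enumerated (4^w states); above that a
# discretized dynamic program is used and adaptively refined until the
# tail probability at `at` is stable to 1e-6 relative.
.scoreTail <- function(score_mat, background, exact_max_width = 8L) {
  w <- ncol(score_mat)
  if (w <= exact_max_width) {
    sums <- 0; probs <- 1
    for (j in seq_len(w)) {
      sums <- as.vector(outer(sums, score_mat[, j], "+"))
      probs <- as.vector(outer(probs, background, "*"))
    }
    o <- order(sums)
    sums <- sums[o]; probs <- probs[o]
    tail_p <- rev(cumsum(rev(probs)))
    function(s) {
      # tail prob of score >= s (1e-9 slack absorbs fp reassociation)
      i <- findInterval(s - 1e-9, sums, left.open = TRUE) + 1L
      ifelse(i > length(sums), 0, tail_p[pmin(i, length(sums))])
    }
  } else {
    rng <- sum(apply(score_mat, 2L, function(cc) diff(range(cc))))
    dp_tail <- function(d) {
      lo <- sum(apply(score_mat, 2L, min))
      dist <- c(1)
      off <- 0L
      for (j in seq_len(w)) {
        ints <- as.integer(round((score_mat[, j] -
                                    min(score_mat[, j])) / d))
        off <- off + as.integer(round(min(score_mat[, j]) / d))
        new <- numeric(length(dist) + max(ints))
        for (a in 1:4) {
          idx <- seq_along(dist) + ints[a]
          new[idx] <- new[idx] + dist * background[a]
        }
        dist <- new
      }
      list(dist = dist, off = off, d = d, lo = lo)
    }
    d <- rng / (1000 * w)
    res <- dp_tail(d)
    repeat {
      res2 <- dp_tail(res$d / 2)
      tailAt <- function(r, s) {
        k <- as.integer(ceiling(s / r$d - 1e-9)) - r$off + 1L
        k <- max(1L, min(k, length(r$dist) + 1L))
        if (k > length(r$dist)) 0 else sum(r$dist[k:length(r$dist)])
      }
      probe <- res$lo + rng * c(0.25, 0.5, 0.75)
      p1 <- vapply(probe, function(s) tailAt(res, s), numeric(1))
      p2 <- vapply(probe, function(s) tailAt(res2, s), numeric(1))
      if (all(abs(p1 - p2) <= 1e-6 * pmax(p2, 1e-300))) break
      res <- res2
      if (res$d < rng / 2^26) break
    }
    r <- res2
    function(s) vapply(s, function(si) {
      k <- as.integer(ceiling(si / r$d - 1e-9)) - r$off + 1L
      k <- max(1L, min(k, length(r$dist) + 1L))
      if (k > length(r$dist)) 0 else sum(r$dist[k:length(r$dist)])
    }, numeric(1))
  }
}

#' Scan sequences with a motif matrix
#'
#' Scores every offset of every sequence with the log-odds (base 2)
#' score of the motif against its background, and keeps occurrences
#' whose exact p-value is at most `p_threshold`. The p-value is the
#' exact probability, under the background model, that a random
#' width-w word scores at least as high; it is computed from the full
#' score distribution (enumerated exactly for widths up to 8,
#' discretized with adaptive refinement above). Scanning is
#' single-stranded on the supplied transcript-sense sequences;
#' windows containing `N` are skipped.
#'
#' @param seqs named character vector of sequences (DNA alphabet;
#'   `U` accepted).
#' @param motif a [MotifMatrix-class].
#' @param p_threshold exact p-value cutoff (default 1e-4).
#' @return data.frame: `sequence_id, start, end` (0-based half-open
#'   within the sequence), `score` (bits), `p`.
#' @export
pwmScan <- function(seqs, motif, p_threshold = 1e-4) {
  stopifnot(is(motif, "MotifMatrix"))
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  w <- motifWidth(motif)
  smat <- log2(motifProbs(motif) / motifBackground(motif))
  tail_fun <- .scoreTail(smat, motifBackground(motif))
  out <- vector("list", length(seqs))
  for (si in seq_along(seqs)) {
    s <- chartr("U", "T", toupper(seqs[[si]]))
    L <- nchar(s)
    if (L < w) next
    idx <- match(strsplit(s, "", fixed = TRUE)[[1L]], .DNA_ALPHABET)
    n_pos <- L - w + 1L
    sc <- numeric(n_pos)
    ok <- rep(TRUE, n_pos)
    for (j in seq_len(w)) {
      aj <- idx[j:(j + n_pos - 1L)]
      ok <- ok & !is.na(aj)
      v <- smat[aj, j]
      v[is.na(v)] <- 0
      sc <- sc + v
    }
    if (!any(ok)) next
    p <- rep(NA_real_, n_pos)
    p[ok] <- tail_fun(sc[ok])
    hit <- which(ok & p <= p_threshold)
    if (length(hit) == 0) next
    out[[si]] <- data.frame(
      sequence_id = names(seqs)[si], start = hit - 1L,
      end = hit - 1L + w, score = sc[hit], p = p[hit],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Map region-relative occurrences to genomic coordinates
#'
#' Occurrences from [pwmScan()] on transcript-sense region sequences
#' (as emitted by [simulateSplicing()]) are lifted to genomic
#' coordinates using the region index; on the minus strand the
#' transcript-sense sequence is the reverse complement of the genomic
#' interval, so positions are reflected.
#'
#' @param occurrences data.frame from [pwmScan()].
#' @param regions region index: `sequence_id, event_id, region, chrom,
#'   g_start, g_end, strand`.
#' @return data.frame: `event_id, region, chrom, start, end, strand,
#'   score, p` (genomic, 0-based half-open).
#' @export
occurrencesToGenomic <- function(occurrences, regions) {
  i <- match(occurrences$sequence_id, regions$sequence_id)
  if (anyNA(i))
    stop("occurrence refers to a sequence absent from the region index")
  r <- regions[i, ]
  plus <- r$strand == "+"
  g_start <- ifelse(plus, r$g_start + occurrences$start,
                    r$g_end - occurrences$end)
  g_end <- ifelse(plus, r$g_start + occurrences$end,
                  r$g_end - occurrences$start)
  data.frame(event_id = r$event_id, region = r$region, chrom = r$chrom,
             start = g_start, end = g_end, strand = r$strand,
             score = occurrences$score, p = occurrences$p,
             stringsAsFactors = FALSE)
}

#' Anchor genomic occurrences at a splice site
#'
#' Converts genomic motif occurrences into offsets relative to the 3'
#' splice site (splice acceptor; negative offsets are intronic /
#' upstream) or the 5' splice site of the alternative exon. On the
#' minus strand, genomic coordinates are reflected so offsets are
#' always in transcript orientation. Occurrences outside the declared
#' regions are dropped and counted (attribute `n_dropped`), not an
#' error.
#'
#' @param events event data.frame (see [readEventsBed()]).
#' @param occurrences genomic occurrences with `event_id, start, end`
#'   (e.g. from [occurrencesToGenomic()]).
#' @param region_spec list with `upstream` (intronic nt before the 3'
#'   splice site, default 300), `exon_into` (nt into the exon, default
#'   50), `downstream` (intronic nt past the 5' splice site, default
#'   300). For `anchor = "3ss"` the axis is
#'   `[-upstream, exon_into)`; for `"5ss"` it is
#'   `[-exon_into, downstream)`.
#' @param anchor `"3ss"` (default) or `"5ss"`.
#' @return data.frame `event_id, off_start, off_end` with attribute
#'   `n_dropped`.
#' @export
anchorOccurrences <- function(events, occurrences,
                              region_spec = list(upstream = 300L,
                                                 exon_into = 50L,
                                                 downstream = 300L),
                              anchor = c("3ss", "5ss")) {
  anchor <- match.arg(anchor)
  i <- match(occurrences$event_id, events$event_id)
  if (anyNA(i)) stop("occurrence refers to an unknown event")
  ev <- events[i, ]
  plus <- ev$strand == "+"
  if (anchor == "3ss") {
    # acceptor: exon start in transcript orientation
    a <- ifelse(plus, ev$alt_start, ev$alt_end)
    off_start <- ifelse(plus, occurrences$start - a, a - occurrences$end)
    lo <- -region_spec$upstream
    hi <- region_spec$exon_into
  } else {
    a <- ifelse(plus, ev$alt_end, ev$alt_start)
    off_start <- ifelse(plus, occurrences$start - a, a - occurrences$end)
    lo <- -region_spec$exon_into
    hi <- region_spec$downstream
  }
  width <- occurrences$end - occurrences$start
  off_end <- off_start + width
  keep <- off_start >= lo & off_end <= hi
  out <- data.frame(event_id = occurrences$event_id[keep],
                    off_start = off_start[keep], off_end = off_end[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Build an RNA map
#'
#' Positional motif-density profile per exon-response group with
#' moving-window Fisher enrichment tests. The density at a position is
#' the fraction of the group's exons with at least one occurrence
#' overlapping it. For every window (length `window`, one center every
#' `step` offsets) the unit of the test is the exon: the 2 x 2 table
#' counts exons with vs without an occurrence in the window, regulated
#' group vs unchanged group, tested one-sided for enrichment in the
#' regulated group (Fisher's exact test / hypergeometric tail).
#'
#' @param groups named character vector: event_id -> group
#'   (`repressed`, `enhanced`, `unchanged`). Every event must carry
#'   exactly one group; the unchanged group is the reference and must
#'   be non-empty.
#' @param anchored anchored occurrences from [anchorOccurrences()].
#' @param axis_range integer length-2 half-open offset range of the
#'   profile (default `c(-300, 50)`, the 3' splice-site axis).
#' @param window window length in nt (default 31).
#' @param step spacing of window centers (default 1).
#' @param anchor label recorded in the result.
#' @return An [RnaMap-class] object.
#' @export
buildRnaMap <- function(groups, anchored, axis_range = c(-300L, 50L),
                        window = 31L, step = 1L, anchor = "3ss") {
  stopifnot(!is.null(names(groups)))
  if (!"unchanged" %in% groups)
    stop("reference-group error: the unchanged group is empty")
  axis <- seq.int(axis_range[1L], axis_range[2L] - 1L)
  n_ax <- length(axis)
  half <- (window - 1L) %/% 2L
  grp_names <- intersect(c("repressed", "enhanced", "unchanged"),
                         unique(groups))
  ev_ids <- names(groups)

  # per-event position coverage (binary), restricted to the axis
  cov <- matrix(FALSE, nrow = length(ev_ids), ncol = n_ax,
                dimnames = list(ev_ids, NULL))
  occ <- anchored[anchored$event_id %in% ev_ids, , drop = FALSE]
  for (k in seq_len(nrow(occ))) {
    s <- max(occ$off_start[k], axis_range[1L])
    e <- min(occ$off_end[k], axis_range[2L])
    if (s < e)
      cov[occ$event_id[k], (s - axis_range[1L] + 1L):(e - axis_range[1L])] <- TRUE
  }
  density <- t(vapply(grp_names, function(g) {
    idx <- groups == g
    colMeans(cov[idx, , drop = FALSE])
  }, numeric(n_ax)))
  rownames(density) <- grp_names

  centers <- seq.int(axis_range[1L] + half, axis_range[2L] - 1L - half,
                     by = step)
  # per-event presence per window: occurrence [s,e) overlaps the window
  # centered at c, i.e. [c-half, c+half+1), iff s <= c+half and e > c-half
  pres <- matrix(FALSE, nrow = length(ev_ids), ncol = length(centers),
                 dimnames = list(ev_ids, NULL))
  for (k in seq_len(nrow(occ))) {
    c_lo <- occ$off_start[k] - half
    c_hi <- occ$off_end[k] - 1L + half
    j <- which(centers >= c_lo & centers <= c_hi)
    if (length(j) > 0) pres[occ$event_id[k], j] <- TRUE
  }
  unch <- groups == "unchanged"
  n_unch <- sum(unch)
  c_cnt <- colSums(pres[unch, , drop = FALSE])
  win <- data.frame(center = centers)
  for (g in setdiff(grp_names, "unchanged")) {
    idx <- groups == g
    n_g <- sum(idx)
    a <- colSums(pres[idx, , drop = FALSE])
    # one-sided Fisher (hypergeometric tail): enrichment in group g
    p <- stats::phyper(a - 1L, a + c_cnt, (n_g - a) + (n_unch - c_cnt),
                       n_g, lower.tail = FALSE)
    or <- (a * (n_unch - c_cnt)) / pmax((n_g - a) * c_cnt, .Machine$double.xmin)
    win[[paste0("with_", g)]] <- a
    win[[paste0("without_", g)]] <- n_g - a
    win[[paste0("with_unchanged")]] <- c_cnt
    win[[paste0("without_unchanged")]] <- n_unch - c_cnt
    win[[paste0("odds_", g)]] <- or
    win[[paste0("p_", g)]] <- p
  }
  new("RnaMap", anchor = anchor, axis = as.integer(axis),
      density = density, windows = win,
      group_sizes = vapply(grp_names, function(g) sum(groups == g),
                           integer(1)),
      window_size = as.integer(window), step = as.integer(step),
      n_dropped = as.integer(attr(anchored, "n_dropped") %||% 0L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Annotate window significance
#'
#' Raw window p-values are reported as-is (matching the published
#' maps); optionally a Benjamini-Hochberg-adjusted column per compared
#' group is appended.
#'
#' @param map an [RnaMap-class].
#' @param adjust append BH-adjusted columns (default FALSE).
#' @return The window data.frame, with `p_adj_*` columns if requested.
#' @export
windowSignificance <- function(map, adjust = FALSE) {
  stopifnot(is(map, "RnaMap"))
  win <- map@windows
  if (adjust) {
    for (col in grep("^p_", names(win), value = TRUE))
      win[[sub("^p_", "p_adj_", col)]] <- p.adjust(win[[col]],
                                                   method = "BH")
  }
  win
}
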
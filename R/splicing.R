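# PSI quantification from junction reads and fragment concentrations,
# delta-PSI testing on pooled counts, regulation classification,
# two-tier shortlisting, event-type summaries and the inclusion /
# skipping proportion test.

.roundHalfUp <- function(x) floor(x + 0.5)

#' Percent spliced-in from junction reads
#'
#' A cassette exon has two inclusion junctions (upstream exon ->
#' cassette, cassette -> downstream exon) and one skipping junction.
#' Inclusion reads are averaged over the two inclusion junctions to
#' correct the two-vs-one junction length asymmetry:
#' `I = (inc1 + inc2)/2`, `PSI = I / (I + skip)`.
#'
#' @param inc1,inc2,skip non-negative integer vectors of junction reads.
#' @param event_id optional event ids for error messages.
#' @return data.frame: `psi` in [0,1] and `effective_coverage = I + skip`.
#' @examples
#' psiFromJunctions(30, 10, 20)  # I = 20 -> psi 0.5
#' @export
psiFromJunctions <- function(inc1, inc2, skip, event_id = NULL) {
  if (any(inc1 < 0 | inc2 < 0 | skip < 0))
    stop("junction counts must be non-negative")
  total <- inc1 + inc2 + skip
  if (any(total == 0)) {
    who <- if (is.null(event_id)) which(total == 0) else
      event_id[total == 0]
    stop(sprintf("undefined PSI: all junction counts zero for %s",
                 paste(head(who, 5L), collapse = ", ")))
  }
  inc <- (inc1 + inc2) / 2
  data.frame(psi = inc / (inc + skip), effective_coverage = inc + skip)
}

#' Percent spliced-in from fragment concentrations
#'
#' For size-resolved RT-PCR products, PSI is the concentration of the
#' larger (exon-included) product relative to the sum of both products.
#'
#' @param c_long,c_short non-negative concentrations of the included
#'   (larger) and skipped (shorter) products.
#' @return numeric PSI in [0,1].
#' @export
psiFromConcentrations <- function(c_long, c_short) {
  if (any(c_long < 0 | c_short < 0))
    stop("concentrations must be non-negative")
  total <- c_long + c_short
  if (any(total == 0))
    stop("undefined PSI: both concentrations are zero")
  c_long / total
}

#' Delta-PSI test between two conditions
#'
#' Replicate junction counts are pooled (summed) per condition; the
#' change is `delta_psi = PSI(B) - PSI(A)` and the p-value comes from a
#' two-sided Fisher exact test on the 2 x 2 table
#' `[rounded inclusion I, skip] x [A, B]`, with `I = (inc1+inc2)/2`
#' rounded half-up. (This defined test replaces the external
#' likelihood-ratio machinery of junction-count tools; the downstream
#' cutoff logic is unchanged.) A zero table margin gives p = 1 with a
#' `degenerate` flag.
#'
#' @param counts_a,counts_b data.frames with columns `event_id, inc1,
#'   inc2, skip` (replicate rows are pooled by event).
#' @param condition_a,condition_b labels recorded in the output.
#' @return data.frame per event: `event_id, psi_a, psi_b, delta_psi,
#'   p, degenerate`.
#' @export
deltaPsiTest <- function(counts_a, counts_b, condition_a = "A",
                         condition_b = "B") {
  pool <- function(d) {
    agg <- aggregate(d[, c("inc1", "inc2", "skip")],
                     by = list(event_id = d$event_id), FUN = sum)
    agg[order(agg$event_id), ]
  }
  a <- pool(counts_a); b <- pool(counts_b)
  if (!identical(a$event_id, b$event_id))
    stop("coverage error: the two conditions cover different event sets")
  ia <- .roundHalfUp((a$inc1 + a$inc2) / 2)
  ib <- .roundHalfUp((b$inc1 + b$inc2) / 2)
  psi_a <- psiFromJunctions(a$inc1, a$inc2, a$skip, a$event_id)$psi
  psi_b <- psiFromJunctions(b$inc1, b$inc2, b$skip, b$event_id)$psi
  n <- nrow(a)
  p <- numeric(n); degen <- logical(n)
  for (i in seq_len(n)) {
    tab <- matrix(c(ia[i], a$skip[i], ib[i], b$skip[i]), nrow = 2L)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      p[i] <- 1; degen[i] <- TRUE
    } else {
      p[i] <- fisher.test(tab)$p.value
    }
  }
  data.frame(event_id = a$event_id, contrast = paste(condition_a,
                                                     condition_b,
                                                     sep = "_vs_"),
             psi_a = psi_a, psi_b = psi_b, delta_psi = psi_b - psi_a,
             p = p, degenerate = degen, stringsAsFactors = FALSE)
}

#' Classify splicing regulation
#'
#' With `delta_psi` oriented knockdown - control, events whose
#' inclusion rises significantly upon knockdown of a repressor are
#' putatively repressed by it: `repressed` when
#' `delta_psi >= delta_cutoff` and `fdr < fdr_cutoff`; `enhanced` when
#' `delta_psi <= -delta_cutoff` and `fdr < fdr_cutoff`; otherwise
#' `unchanged`.
#'
#' @param records data.frame from [deltaPsiTest()] with an `fdr` column
#'   (fill with [bhFdr()] over all tested events first).
#' @param delta_cutoff minimum |delta PSI| (default 0.2, i.e. the 20%
#'   splice-change rule).
#' @param fdr_cutoff FDR threshold (default 0.05).
#' @return `records` with a `regulation_class` column.
#' @export
classifyRegulation <- function(records, delta_cutoff = 0.2,
                               fdr_cutoff = 0.05) {
  if (!"fdr" %in% names(records))
    stop("records must carry an 'fdr' column (apply bhFdr to p first)")
  sig <- records$fdr < fdr_cutoff
  records$regulation_class <- ifelse(
    sig & records$delta_psi >= delta_cutoff, "repressed",
    ifelse(sig & records$delta_psi <= -delta_cutoff, "enhanced",
           "unchanged"))
  records
}

#' Shortlist splicing events across two contrasts
#'
#' Events responding to regulator loss are shortlisted in two tiers:
#' tier 1 = significant in the regulator-knockdown contrast at
#' `base_cutoff` AND also significantly changed in the senescence
#' contrast; tier 2 = significant upon regulator loss but unchanged in
#' senescence, required to pass the stricter `strict_cutoff`. Output is
#' sorted by |delta PSI| in the regulator contrast, descending, ties by
#' event id.
#'
#' @param records_regulator,records_senescence classified records (from
#'   [classifyRegulation()]) over the same event universe.
#' @param base_cutoff base |delta PSI| cutoff (default 0.2).
#' @param strict_cutoff stricter cutoff for senescence-independent
#'   events (default 0.3).
#' @param fdr_cutoff FDR threshold (default 0.05).
#' @return data.frame: `event_id, delta_psi, tier` (1 or 2).
#' @export
shortlistEvents <- function(records_regulator, records_senescence,
                            base_cutoff = 0.2, strict_cutoff = 0.3,
                            fdr_cutoff = 0.05) {
  r <- records_regulator[order(records_regulator$event_id), ]
  s <- records_senescence[order(records_senescence$event_id), ]
  if (!identical(r$event_id, s$event_id))
    stop("coverage error: contrasts cover different event universes")
  sig_r <- r$fdr < fdr_cutoff & abs(r$delta_psi) >= base_cutoff
  sig_s <- s$fdr < fdr_cutoff & abs(s$delta_psi) >= base_cutoff
  tier <- rep(NA_integer_, nrow(r))
  tier[sig_r & sig_s] <- 1L
  tier[sig_r & !sig_s & abs(r$delta_psi) >= strict_cutoff] <- 2L
  keep <- !is.na(tier)
  out <- data.frame(event_id = r$event_id[keep],
                    delta_psi = r$delta_psi[keep], tier = tier[keep],
                    stringsAsFactors = FALSE)
  out[order(-abs(out$delta_psi), out$event_id), ]
}

#' One-sided proportion test for inclusion direction
#'
#' Pearson chi-square test of the observed count of
#' inclusion-increasing events against an expected proportion of 0.5,
#' one-sided toward excess inclusion: `chi2 = sum (obs - n/2)^2 /
#' (n/2)` over the two cells; the one-sided p is half the chi-square(1)
#' tail when the observed proportion exceeds 0.5, and 1 minus that half
#' otherwise.
#'
#' @param n_inclusion_up events with increased inclusion.
#' @param n_total total events.
#' @return list: `chi2`, `p_one_sided`, `proportion`.
#' @examples
#' inclusionProportionTest(70, 100)  # chi2 = 16
#' @export
inclusionProportionTest <- function(n_inclusion_up, n_total) {
  if (n_total < 1) stop("sample-size error: n_total must be >= 1")
  if (n_inclusion_up < 0 || n_inclusion_up > n_total)
    stop("n_inclusion_up must lie in 0..n_total")
  e <- n_total / 2
  chi2 <- (n_inclusion_up - e)^2 / e + ((n_total - n_inclusion_up) - e)^2 / e
  half_tail <- pchisq(chi2, df = 1, lower.tail = FALSE) / 2
  prop <- n_inclusion_up / n_total
  p <- if (prop > 0.5) half_tail else 1 - half_tail
  list(chi2 = chi2, p_one_sided = p, proportion = prop)
}

#' Summarize alternative-splicing event types
#'
#' @param events event data.frame (see [readEventsBed()]).
#' @return data.frame over the five event types (SE, RI, MXE, A5SS,
#'   A3SS): `event_type, n, fraction`.
#' @export
summarizeEventTypes <- function(events) {
  bad <- setdiff(unique(events$event_type), .EVENT_TYPES)
  if (length(bad) > 0)
    stop(sprintf("format error: unknown event type(s) %s",
                 paste(bad, collapse = ", ")))
  n <- table(factor(events$event_type, levels = .EVENT_TYPES))
  total <- sum(n)
  data.frame(event_type = .EVENT_TYPES, n = as.integer(n),
             fraction = if (total > 0) as.numeric(n) / total else
               rep(0, length(.EVENT_TYPES)),
             stringsAsFactors = FALSE)
}
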
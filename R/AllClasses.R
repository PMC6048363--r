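#' @import methods
#' @importFrom stats median mad sd density fisher.test pchisq kmeans
#'   p.adjust rnorm rbinom runif setNames quantile var complete.cases
#'   aggregate phyper pt reshape
#' @importFrom utils read.csv read.delim write.table head
NULL

.PLATE_ROLES <- c("sample", "negative_control", "positive_control", "empty")
.EVENT_TYPES <- c("SE", "RI", "MXE", "A5SS", "A3SS")
.DNA_ALPHABET <- c("A", "C", "G", "T")

#' PlateSet: per-well readouts of a multi-well screen
#'
#' Container for one or more 96-well plates of a high-content screen.
#' Each row of the `wells` table is one well, identified by
#' `(plate_id, replicate, row, col)`, annotated with a well role
#' (sample, negative control, positive control, empty), the transfected
#' siRNA and targeted gene, and one numeric column per readout
#' (e.g. percent IL-8 positive cells).
#'
#' @slot wells data.frame with the columns `plate_id`, `replicate`,
#'   `row`, `col`, `well_role`, `sirna_id`, `gene_id` plus one numeric
#'   column per readout.
#' @slot readouts character vector naming the readout columns.
#' @slot n_row,n_col plate geometry (defaults 8 x 12).
#'
#' @seealso [readPlateTable()], [simulateScreen()], [bScore()], [npi()]
#' @export
setClass("PlateSet",
  representation(
    wells = "data.frame",
    readouts = "character",
    n_row = "integer",
    n_col = "integer"
  )
)

setValidity("PlateSet", function(object) {
  w <- object@wells
  need <- c("plate_id", "replicate", "row", "col", "well_role",
            "sirna_id", "gene_id")
  miss <- setdiff(need, names(w))
  if (length(miss) > 0)
    return(sprintf("missing well columns: %s", paste(miss, collapse = ", ")))
  miss_r <- setdiff(object@readouts, names(w))
  if (length(miss_r) > 0)
    return(sprintf("missing readout columns: %s",
                   paste(miss_r, collapse = ", ")))
  if (length(object@readouts) == 0)
    return("at least one readout column is required")
  bad_role <- setdiff(unique(w$well_role), .PLATE_ROLES)
  if (length(bad_role) > 0)
    return(sprintf("unknown well_role values: %s",
                   paste(bad_role, collapse = ", ")))
  if (nrow(w) > 0) {
    if (any(w$row < 1L | w$row > object@n_row))
      return(sprintf("row indices must lie in 1..%d", object@n_row))
    if (any(w$col < 1L | w$col > object@n_col))
      return(sprintf("col indices must lie in 1..%d", object@n_col))
    key <- paste(w$plate_id, w$replicate, w$row, w$col)
    if (anyDuplicated(key)) {
      d <- w[duplicated(key), , drop = FALSE][1L, ]
      return(sprintf(
        "duplicate well: plate %s replicate %s row %s col %s",
        d$plate_id, d$replicate, d$row, d$col))
    }
    for (r in object@readouts)
      if (!is.numeric(w[[r]]))
        return(sprintf("readout column '%s' is not numeric", r))
  }
  TRUE
})

#' Construct a PlateSet
#'
#' @param wells data.frame of wells (see [PlateSet-class]).
#' @param readouts names of the readout columns; by default every numeric
#'   column that is not one of the well annotation columns.
#' @param n_row,n_col plate geometry.
#' @return A validated [PlateSet-class] object.
#' @export
PlateSet <- function(wells, readouts = NULL, n_row = 8L, n_col = 12L) {
  wells <- as.data.frame(wells)
  anno <- c("plate_id", "replicate", "row", "col", "well_role",
            "sirna_id", "gene_id")
  miss <- setdiff(anno, names(wells))
  if (length(miss) > 0)
    stop(sprintf("missing well columns: %s", paste(miss, collapse = ", ")))
  if (is.null(readouts)) {
    cand <- setdiff(names(wells), anno)
    readouts <- cand[vapply(wells[cand], is.numeric, logical(1))]
  }
  wells$plate_id <- as.character(wells$plate_id)
  wells$replicate <- as.integer(wells$replicate)
  wells$row <- as.integer(wells$row)
  wells$col <- as.integer(wells$col)
  wells$well_role <- as.character(wells$well_role)
  wells$sirna_id <- as.character(wells$sirna_id)
  wells$gene_id <- as.character(wells$gene_id)
  new("PlateSet", wells = wells, readouts = as.character(readouts),
      n_row = as.integer(n_row), n_col = as.integer(n_col))
}

#' @describeIn PlateSet-class the per-well table.
#' @param x,object a `PlateSet`.
#' @export
setGeneric("wells", function(x) standardGeneric("wells"))

#' @rdname PlateSet-class
#' @export
setMethod("wells", "PlateSet", function(x) x@wells)

#' @describeIn PlateSet-class names of the readout columns.
#' @export
setGeneric("readoutNames", function(x) standardGeneric("readoutNames"))

#' @rdname PlateSet-class
#' @export
setMethod("readoutNames", "PlateSet", function(x) x@readouts)

#' @describeIn PlateSet-class unique (plate_id, replicate) combinations.
#' @export
setGeneric("plateIds", function(x) standardGeneric("plateIds"))

#' @rdname PlateSet-class
#' @export
setMethod("plateIds", "PlateSet", function(x) {
  unique(x@wells[, c("plate_id", "replicate")])
})

setMethod("show", "PlateSet", function(object) {
  ids <- plateIds(object)
  cat(sprintf("PlateSet: %d plate(s) x %d replicate layout, %d wells\n",
              length(unique(ids$plate_id)),
              length(unique(ids$replicate)), nrow(object@wells)))
  cat(sprintf("  geometry: %d x %d\n", object@n_row, object@n_col))
  cat(sprintf("  readouts: %s\n", paste(object@readouts, collapse = ", ")))
  tab <- table(object@wells$well_role)
  cat(sprintf("  roles: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

#' MotifMatrix: position probability model of an RNA-binding motif
#'
#' Column-stochastic 4 x width matrix over the DNA alphabet (RNA motifs
#' are canonicalized with U -> T), with a pseudocount applied at
#' construction and a background composition used for log-odds scoring.
#'
#' @slot probs 4 x width numeric matrix, rows A/C/G/T, columns summing
#'   to 1 after pseudocount normalization.
#' @slot background length-4 strictly positive simplex vector.
#' @slot pseudocount the pseudocount that was added per cell.
#'
#' @seealso [motifMatrix()], [pwmScan()]
#' @export
setClass("MotifMatrix",
  representation(
    probs = "matrix",
    background = "numeric",
    pseudocount = "numeric"
  )
)

setValidity("MotifMatrix", function(object) {
  p <- object@probs
  if (nrow(p) != 4L || is.null(rownames(p)) ||
      !identical(rownames(p), .DNA_ALPHABET))
    return("probs must be a 4 x width matrix with rows A, C, G, T")
  if (ncol(p) < 1L) return("motif width must be >= 1")
  cs <- colSums(p)
  if (any(abs(cs - 1) > 1e-9))
    return("motif columns must sum to 1 (after pseudocount normalization)")
  b <- object@background
  if (length(b) != 4L || any(b <= 0) || abs(sum(b) - 1) > 1e-9)
    return("background must be a strictly positive length-4 simplex vector")
  if (object@pseudocount <= 0) return("pseudocount must be > 0")
  TRUE
})

#' Construct a MotifMatrix
#'
#' @param probs 4 x width matrix of letter probabilities (or counts);
#'   rows in A, C, G, T order (a `U` row name is accepted and renamed
#'   to `T`). Columns are renormalized after adding `pseudocount`.
#' @param background length-4 background composition (default uniform).
#' @param pseudocount pseudocount added to each cell before column
#'   normalization; must be positive.
#' @return A validated [MotifMatrix-class] object.
#' @examples
#' m <- motifMatrix(matrix(c(0, 1, 0, 0,
#'                           0, 1, 0, 0,
#'                           0, 0, 0, 1), nrow = 4))
#' motifWidth(m)
#' @export
motifMatrix <- function(probs, background = rep(0.25, 4),
                        pseudocount = 1e-3) {
  probs <- as.matrix(probs)
  if (is.null(rownames(probs))) rownames(probs) <- .DNA_ALPHABET
  rownames(probs) <- sub("^U$", "T", toupper(rownames(probs)))
  probs <- probs[.DNA_ALPHABET, , drop = FALSE]
  if (any(probs < 0) || any(!is.finite(probs)))
    stop("motif probabilities must be finite and non-negative")
  probs <- probs + pseudocount
  probs <- sweep(probs, 2L, colSums(probs), "/")
  background <- background / sum(background)
  new("MotifMatrix", probs = probs, background = background,
      pseudocount = pseudocount)
}

#' @describeIn MotifMatrix-class motif width (number of columns).
#' @param x,object a `MotifMatrix`.
#' @export
setGeneric("motifWidth", function(x) standardGeneric("motifWidth"))

#' @rdname MotifMatrix-class
#' @export
setMethod("motifWidth", "MotifMatrix", function(x) ncol(x@probs))

#' @describeIn MotifMatrix-class the normalized probability matrix.
#' @export
setGeneric("motifProbs", function(x) standardGeneric("motifProbs"))

#' @rdname MotifMatrix-class
#' @export
setMethod("motifProbs", "MotifMatrix", function(x) x@probs)

#' @describeIn MotifMatrix-class the background composition.
#' @export
setGeneric("motifBackground", function(x) standardGeneric("motifBackground"))

#' @rdname MotifMatrix-class
#' @export
setMethod("motifBackground", "MotifMatrix", function(x) x@background)

setMethod("show", "MotifMatrix", function(object) {
  cat(sprintf("MotifMatrix: width %d, pseudocount %g\n",
              ncol(object@probs), object@pseudocount))
  consensus <- paste(rownames(object@probs)[apply(object@probs, 2L,
                                                  which.max)],
                     collapse = "")
  cat(sprintf("  consensus: %s\n", consensus))
  cat(sprintf("  background: %s\n",
              paste(sprintf("%s=%.3f", .DNA_ALPHABET, object@background),
                    collapse = " ")))
})

#' RnaMap: positional motif-density profile with windowed enrichment
#'
#' Result of [buildRnaMap()]: per-group motif density along an axis of
#' offsets anchored at a splice site, and per-window 2 x 2 Fisher tests
#' of motif presence (regulated vs unregulated exons).
#'
#' @slot anchor which splice site the offsets are relative to
#'   (`"3ss"` or `"5ss"`).
#' @slot axis integer offsets covered by the profile.
#' @slot density group x position matrix; entry = fraction of the
#'   group's exons with at least one motif occurrence overlapping the
#'   position.
#' @slot windows data.frame of moving-window tests (center, 2 x 2 cells,
#'   odds ratio and one-sided p per compared group).
#' @slot group_sizes named integer vector of exons per group.
#' @slot window_size,step window geometry used.
#' @slot n_dropped occurrences falling outside all declared regions.
#'
#' @export
setClass("RnaMap",
  representation(
    anchor = "character",
    axis = "integer",
    density = "matrix",
    windows = "data.frame",
    group_sizes = "integer",
    window_size = "integer",
    step = "integer",
    n_dropped = "integer"
  )
)

#' @describeIn RnaMap-class the moving-window test table.
#' @param x,object an `RnaMap`.
#' @export
setGeneric("mapWindows", function(x) standardGeneric("mapWindows"))

#' @rdname RnaMap-class
#' @export
setMethod("mapWindows", "RnaMap", function(x) x@windows)

#' @describeIn RnaMap-class the group x position density matrix.
#' @export
setGeneric("mapDensity", function(x) standardGeneric("mapDensity"))

#' @rdname RnaMap-class
#' @export
setMethod("mapDensity", "RnaMap", function(x) x@density)

setMethod("show", "RnaMap", function(object) {
  cat(sprintf("RnaMap anchored at %s: offsets %d..%d, %d-nt windows (step %d)\n",
              object@anchor, min(object@axis), max(object@axis),
              object@window_size, object@step))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", names(object@group_sizes),
                            object@group_sizes), collapse = ", ")))
  if (nrow(object@windows) > 0 && "p_repressed" %in% names(object@windows)) {
    i <- which.min(object@windows$p_repressed)
    cat(sprintf("  min-p window (repressed vs unchanged): center %+d, p = %.3g\n",
                object@windows$center[i], object@windows$p_repressed[i]))
  }
  if (object@n_dropped > 0)
    cat(sprintf("  %d occurrence(s) outside declared regions were dropped\n",
                object@n_dropped))
})
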
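#' Barrier ensemble: one activation barrier per MD snapshot
#'
#' A \code{barrier_ensemble} holds the per-conformation activation barriers
#' of one enzyme system computed with one QM-region size, in sampling
#' (chronological) order.  It is a data frame with columns
#' \code{conformation_id} (unique, nonempty labels), \code{sample_time}
#' (ns, optional, \code{NA} allowed) and \code{barrier} (kcal/mol, finite
#' and strictly positive), plus \code{system_label} and \code{qm_region}
#' attributes.
#'
#' Barriers must be strictly positive because the disproportionate effect
#' divides by a Boltzmann-weighted average; a zero or negative average would
#' make that statistic meaningless.
#'
#' @param barrier Numeric vector of activation barriers in kcal/mol.
#' @param conformation_id Character vector of snapshot labels; defaults to
#'   \code{"c1"}, \code{"c2"}, ... in sampling order.
#' @param sample_time Optional numeric vector of sampling times in ns
#'   (non-negative); recycled \code{NA} if omitted.
#' @param system_label Label for the enzyme/substrate system.
#' @param qm_region \code{"small"} or \code{"big"}.
#'
#' @return An object of classes \code{barrier_ensemble} and
#'   \code{data.frame}.
#' @examples
#' barrier_ensemble(c(18.7, 21.3, 20.2), system_label = "FAcD-FAc",
#'                  qm_region = "small")
#' @export
barrier_ensemble <- function(barrier, conformation_id = NULL,
                             sample_time = NULL, system_label = "system",
                             qm_region = c("small", "big")) {
  qm_region <- match.arg(qm_region)
  n <- length(barrier)
  if (n == 0L) stop("empty ensemble", call. = FALSE)
  if (is.null(conformation_id)) conformation_id <- paste0("c", seq_len(n))
  conformation_id <- as.character(conformation_id)
  if (is.null(sample_time)) sample_time <- rep(NA_real_, n)
  sample_time <- as.numeric(sample_time)
  if (length(conformation_id) != n || length(sample_time) != n) {
    stop("conformation_id, sample_time and barrier lengths differ",
         call. = FALSE)
  }
  df <- data.frame(conformation_id = conformation_id,
                   sample_time = sample_time,
                   barrier = as.numeric(barrier),
                   stringsAsFactors = FALSE)
  attr(df, "system_label") <- as.character(system_label)[1L]
  attr(df, "qm_region") <- qm_region
  class(df) <- c("barrier_ensemble", "data.frame")
  validate_barrier_ensemble(df)
}

validate_barrier_ensemble <- function(x) {
  if (nrow(x) == 0L) stop("empty ensemble", call. = FALSE)
  if (any(!nzchar(x$conformation_id)) || anyNA(x$conformation_id)) {
    stop("invalid conformation_id: labels must be nonempty", call. = FALSE)
  }
  if (anyDuplicated(x$conformation_id)) {
    dup <- x$conformation_id[duplicated(x$conformation_id)][1L]
    stop(sprintf("duplicate conformation_id '%s'", dup), call. = FALSE)
  }
  if (any(!is.finite(x$barrier)) || any(x$barrier <= 0)) {
    stop("invalid barrier: barriers must be finite and strictly positive",
         call. = FALSE)
  }
  st <- x$sample_time
  if (any(!is.na(st) & (st < 0 | !is.finite(st)))) {
    stop("invalid sample_time: times must be finite and non-negative",
         call. = FALSE)
  }
  x
}

#' @export
print.barrier_ensemble <- function(x, ...) {
  cat(sprintf("Barrier ensemble '%s' (%s QM region): %d conformation(s)\n",
              attr(x, "system_label"), attr(x, "qm_region"), nrow(x)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Conformation-matched small-QM and big-QM barriers
#'
#' A \code{paired_ensemble} holds, for each MD snapshot, the activation
#' barrier computed with a small (pre-screening) QM region and the barrier
#' of the same conformation computed with a big QM region, in sampling
#' order.
#'
#' @param barrier_small,barrier_big Numeric vectors of barriers in kcal/mol
#'   (finite, strictly positive), matched one-to-one by position.
#' @inheritParams barrier_ensemble
#'
#' @return An object of classes \code{paired_ensemble} and
#'   \code{data.frame} with columns \code{conformation_id},
#'   \code{sample_time}, \code{barrier_small}, \code{barrier_big}.
#' @examples
#' paired_ensemble(barrier_small = c(20, 19, 22),
#'                 barrier_big   = c(15, 14, 17))
#' @export
paired_ensemble <- function(barrier_small, barrier_big,
                            conformation_id = NULL, sample_time = NULL,
                            system_label = "system") {
  n <- length(barrier_small)
  if (n == 0L) stop("empty ensemble", call. = FALSE)
  if (length(barrier_big) != n) {
    stop("barrier_small and barrier_big must be matched one-to-one",
         call. = FALSE)
  }
  if (is.null(conformation_id)) conformation_id <- paste0("c", seq_len(n))
  if (is.null(sample_time)) sample_time <- rep(NA_real_, n)
  df <- data.frame(conformation_id = as.character(conformation_id),
                   sample_time = as.numeric(sample_time),
                   barrier_small = as.numeric(barrier_small),
                   barrier_big = as.numeric(barrier_big),
                   stringsAsFactors = FALSE)
  attr(df, "system_label") <- as.character(system_label)[1L]
  class(df) <- c("paired_ensemble", "data.frame")
  validate_paired_ensemble(df)
}

validate_paired_ensemble <- function(x) {
  if (nrow(x) == 0L) stop("empty ensemble", call. = FALSE)
  if (anyDuplicated(x$conformation_id)) {
    dup <- x$conformation_id[duplicated(x$conformation_id)][1L]
    stop(sprintf("duplicate conformation_id '%s'", dup), call. = FALSE)
  }
  for (col in c("barrier_small", "barrier_big")) {
    if (any(!is.finite(x[[col]])) || any(x[[col]] <= 0)) {
      stop(sprintf("invalid barrier in column '%s': barriers must be finite and strictly positive",
                   col), call. = FALSE)
    }
  }
  x
}

#' @export
print.paired_ensemble <- function(x, ...) {
  cat(sprintf("Paired small/big QM barrier ensemble '%s': %d conformation(s)\n",
              attr(x, "system_label"), nrow(x)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Extract one QM-region side of a paired ensemble
#'
#' @param paired A \code{\link{paired_ensemble}}.
#' @param qm_region \code{"small"} or \code{"big"}.
#' @return A \code{\link{barrier_ensemble}} in the same sampling order.
#' @export
ensemble_side <- function(paired, qm_region = c("small", "big")) {
  qm_region <- match.arg(qm_region)
  stopifnot(inherits(paired, "paired_ensemble"))
  col <- paste0("barrier_", qm_region)
  barrier_ensemble(paired[[col]],
                   conformation_id = paired$conformation_id,
                   sample_time = paired$sample_time,
                   system_label = attr(paired, "system_label"),
                   qm_region = qm_region)
}

#' Lowest-barrier conformation
#'
#' Returns the record with the smallest activation barrier; ties are broken
#' by earliest sampling order, matching the tie rule used when the
#' disproportionate effect drops the lowest-barrier conformation.
#'
#' @param ensemble A \code{\link{barrier_ensemble}}.
#' @return A list with elements \code{conformation_id}, \code{barrier} and
#'   \code{index} (position in sampling order).
#' @examples
#' e <- barrier_ensemble(c(12, 9.5, 9.5), c("a", "b", "c"))
#' min_barrier(e)   # "b": earliest of the tied minima
#' @export
min_barrier <- function(ensemble) {
  stopifnot(inherits(ensemble, "barrier_ensemble"))
  if (nrow(ensemble) == 0L) stop("empty ensemble", call. = FALSE)
  i <- which.min(ensemble$barrier)   # which.min is first-match: earliest wins
  list(conformation_id = ensemble$conformation_id[i],
       barrier = ensemble$barrier[i],
       index = i)
}
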
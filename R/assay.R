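#' @include AllClasses.R
NULL

#' CMTMR proliferation score
#'
#' Normalized proliferation over the assay window:
#' \code{100 * (signal_t0 - signal_t48) / (refSignal_t0 - refSignal_t48)},
#' where signals are geometric means of the CMTMR label in the transfected
#' population. The reference condition (inactive scaffold) maps to 100 and
#' an unchanged signal maps to 0. Scale-invariant: multiplying all signals
#' by a positive constant leaves scores unchanged.
#'
#' @param t0,t48 condition signals at 0 h and 48 h (same arbitrary units).
#' @param refT0,refT48 reference-condition signals.
#' @return The proliferation score (vectorized over conditions).
#' @examples
#' proliferationScore(200, 100, 200, 100)  # 100, the reference itself
#' proliferationScore(200, 200, 200, 100)  # 0, no signal loss
#' @export
proliferationScore <- function(t0, t48, refT0, refT48) {
    if (any(c(t0, t48, refT0, refT48) <= 0))
        stop("signals must be positive")
    dref <- refT0 - refT48
    if (any(dref == 0)) stop("degenerate reference: zero signal change")
    100 * (t0 - t48) / dref
}

#' One-tailed t test of a condition mean against a reference value
#'
#' Tests whether the mean replicate score is smaller than the reference
#' (normalized to 100): \code{t = (reference - mean) / SEM} with the SEM
#' of \code{\link{semOfMean}} and \code{n - 1} degrees of freedom; the
#' one-tailed p value is the upper tail of the Student t distribution and
#' the hypothesis is accepted at p <= alpha. A zero SEM (all replicates
#' equal) is degenerate: p tends to 0 if all scores sit below the
#' reference, to 1 if above, and is 0.5 at the reference; the result is
#' flagged.
#'
#' @param scores numeric replicate scores (length >= 2).
#' @param reference reference value (default 100).
#' @param alpha significance level (default 0.05).
#' @return A list: mean, sem, n, t, p, significant, degenerate.
#' @examples
#' oneTailedTVsReference(c(80, 85, 90, 85))  # t = 7.35, p = 0.0026
#' @export
oneTailedTVsReference <- function(scores, reference = 100, alpha = 0.05) {
    if (length(scores) < 2L) stop("need at least two replicates")
    if (!all(is.finite(scores))) stop("non-finite scores")
    n <- length(scores)
    m <- mean(scores)
    s <- semOfMean(scores)
    if (s == 0) {
        p <- if (m < reference) 0 else if (m > reference) 1 else 0.5
        return(list(mean = m, sem = s, n = n,
                    t = if (m == reference) 0 else Inf * sign(reference - m),
                    p = p, significant = p <= alpha, degenerate = TRUE))
    }
    tval <- (reference - m) / s
    p <- pt(tval, df = n - 1, lower.tail = FALSE)
    list(mean = m, sem = s, n = n, t = tval, p = p,
         significant = p <= alpha, degenerate = FALSE)
}

#' Summarize nuclear NFAT signal per condition
#'
#' Mean and SEM of per-cell nuclear mean fluorescence (8-bit scale, 0-255)
#' for each condition; a condition with a single cell reports an undefined
#' (NA) SEM.
#'
#' @param records data frame with columns \code{condition} and
#'   \code{value}.
#' @param conditions optional conditions to require; an absent requested
#'   condition is an error.
#' @return A data frame: condition, n, mean, sem.
#' @examples
#' nfatSummary(data.frame(condition = "CnA*", value = c(100, 110, 120, 130)))
#' @export
nfatSummary <- function(records, conditions = NULL) {
    if (!all(c("condition", "value") %in% names(records)))
        stop("records needs columns 'condition' and 'value'")
    if (!nrow(records)) stop("no records")
    if (any(records$value < 0 | records$value > 255))
        stop("pixel values must lie in [0, 255]")
    if (!is.null(conditions)) {
        missing <- setdiff(conditions, unique(records$condition))
        if (length(missing))
            stop("missing condition(s): ", paste(missing, collapse = ", "))
        records <- records[records$condition %in% conditions, , drop = FALSE]
    }
    out <- do.call(rbind, lapply(split(records$value, records$condition),
        function(v) data.frame(n = length(v), mean = mean(v),
                               sem = if (length(v) > 1) semOfMean(v)
                                     else NA_real_)))
    data.frame(condition = rownames(out), out, row.names = NULL)
}
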
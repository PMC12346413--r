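#' Two-point doubling time
#'
#' \eqn{DT = (t_2 - t_1) \ln 2 / \ln(n_2 / n_1)} in hours. A negative DT
#' (declining counts) is returned with a \code{"decline"} attribute rather
#' than an error; equal counts leave DT undefined.
#'
#' @param t1,t2 times in hours, \code{t2 > t1}.
#' @param n1,n2 positive cell counts.
#' @return doubling time in hours.
#' @export
doublingTimeTwoPoint <- function(t1, n1, t2, n2) {
    if (t2 <= t1) stop("t2 must exceed t1")
    if (n1 <= 0 || n2 <= 0) stop("counts must be positive")
    if (n2 == n1) stop("doubling time undefined: counts unchanged")
    dt <- (t2 - t1) * log(2) / log(n2 / n1)
    if (dt < 0) attr(dt, "decline") <- TRUE
    dt
}

#' Doubling time by exponential (log-linear) curve fitting
#'
#' Least-squares fit of \eqn{\ln(count) = \ln N_0 + k t}; doubling time is
#' \eqn{\ln 2 / k} and the fit quality is the r-squared of the log-linear
#' regression. Log-linear least squares is closed-form and deterministic,
#' which is why it is used instead of a nonlinear exponential fit. A
#' non-positive rate flags a declining series (DT reported negative, with a
#' warning).
#'
#' @param time numeric vector of times (hours), >= 3 points.
#' @param count positive cell counts, same length.
#' @return list with \code{dt_h}, \code{rate} (per hour), \code{r2},
#'   \code{n0} (fitted intercept count), \code{decline}.
#' @export
doublingTimeFit <- function(time, count) {
    if (length(time) != length(count) || length(time) < 3L)
        stop("need >= 3 (time, count) points")
    if (any(count <= 0)) stop("counts must be positive")
    fit <- stats::lm(log(count) ~ time)
    k <- unname(stats::coef(fit)[2L])
    decline <- k <= 0
    if (decline)
        warning("non-positive growth rate: series is declining")
    # noiseless series are legitimate here; silence lm's perfect-fit note
    r2 <- suppressWarnings(summary(fit)$r.squared)
    list(dt_h = log(2) / k, rate = k,
         r2 = r2,
         n0 = exp(unname(stats::coef(fit)[1L])),
         decline = decline)
}

#' Read growth series and report doubling times
#'
#' Input TSV columns: \code{time_h}, \code{count}, \code{series_label}
#' (e.g. one label per cell line x passage). Each series is fitted with
#' [doublingTimeFit()].
#'
#' @param path growth TSV.
#' @return data.frame per series: \code{series_label}, \code{n_points},
#'   \code{dt_h}, \code{rate}, \code{r2}, \code{decline}.
#' @export
growthReport <- function(path) {
    if (!file.exists(path)) stop("growth file not found: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    req <- c("time_h", "count", "series_label")
    if (!all(req %in% colnames(tab)))
        stop("growth file needs columns: ", paste(req, collapse = ", "))
    do.call(rbind, lapply(split(tab, tab$series_label), function(s) {
        f <- doublingTimeFit(s$time_h, s$count)
        data.frame(series_label = s$series_label[1L],
                   n_points = nrow(s), dt_h = f$dt_h, rate = f$rate,
                   r2 = f$r2, decline = f$decline, row.names = NULL)
    }))
}
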
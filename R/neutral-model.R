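# Sloan neutral community model: fit the immigration parameter m to the
# occurrence-frequency vs mean-relative-abundance relationship, compute the
# fit R2 and Nm, a 95% envelope, and the above/neutral/below partition.

#' Prepare NCM input from a count table
#'
#' Per OTU: mean TSS relative abundance across samples, occurrence
#' frequency (presence fraction), plus the mean library size `N` and the
#' detection limit `d = 1/N`. OTUs absent everywhere are excluded.
#'
#' @param table count matrix with >= 2 samples.
#' @param detection `"mean"` uses `d = 1/mean(library sizes)`; `"per_sample"`
#'   uses the mean of per-sample detection limits `1/N_s`.
#' @return list with `data` (data.frame `otu_id`, `p`, `freq`), `N`, `d`,
#'   `n_samples`.
#' @export
ncm_prepare <- function(table, detection = c("mean", "per_sample")) {
  detection <- match.arg(detection)
  if (ncol(table) < 2L) stop("need >= 2 samples")
  libs <- colSums(table)
  rel <- tss_normalize(table)
  p <- rowMeans(rel)
  freq <- rowMeans(table > 0)
  keep <- freq > 0
  N <- mean(libs)
  d <- if (detection == "mean") 1 / N else mean(1 / libs)
  list(data = data.frame(otu_id = rownames(table)[keep],
                         p = p[keep], freq = freq[keep],
                         stringsAsFactors = FALSE, row.names = NULL),
       N = N, d = d, n_samples = ncol(table))
}

#' Neutral prediction of occurrence frequency
#'
#' Sloan's beta-law prediction: the frequency with which a taxon of mean
#' relative abundance `p` exceeds the detection limit `d` is
#' `1 - pbeta(d, N m p, N m (1 - p))`.
#'
#' @param p mean relative abundances.
#' @param m immigration probability.
#' @param N community (library) size.
#' @param d detection limit.
#' @return predicted frequencies.
#' @export
ncm_predict <- function(p, m, N, d) {
  1 - pbeta(d, N * m * p, N * m * (1 - p))
}

wilson_interval <- function(phat, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  cbind(lower = pmax(center - half, 0), upper = pmin(center + half, 1))
}

#' Fit the Sloan neutral community model
#'
#' Estimates the immigration probability `m` by least squares of observed
#' occurrence frequency on the beta-law prediction, over all included OTUs
#' (untransformed frequency, no binning). The 95% envelope is a Wilson
#' binomial prediction interval around the predicted frequency at the
#' realized number of samples; OTUs above/below it are flagged.
#'
#' @param input result of [ncm_prepare()].
#' @param conf envelope confidence level.
#' @return list with `m`, `Nm`, `N`, `R2`, and `data` (per-OTU `p`, `freq`,
#'   `predicted`, `lower`, `upper`, `partition`).
#' @export
ncm_fit <- function(input, conf = 0.95) {
  dat <- input$data
  if (nrow(dat) < 10L ||
      diff(range(log10(dat$p))) < 1) {
    warning("few OTUs or narrow abundance range; fit may be unstable")
  }
  sse <- function(log10m) {
    m <- 10^log10m
    sum((dat$freq - ncm_predict(dat$p, m, input$N, input$d))^2)
  }
  opt <- optimize(sse, interval = c(-8, 0), tol = 1e-8)
  m <- min(max(10^opt$minimum, 1e-8), 1)
  pred <- ncm_predict(dat$p, m, input$N, input$d)
  sst <- sum((dat$freq - mean(dat$freq))^2)
  r2 <- 1 - opt$objective / sst
  ci <- wilson_interval(pred, input$n_samples, conf)
  dat$predicted <- pred
  dat$lower <- ci[, "lower"]
  dat$upper <- ci[, "upper"]
  dat$partition <- ifelse(dat$freq > dat$upper + 1e-9, "above",
                   ifelse(dat$freq < dat$lower - 1e-9, "below", "neutral"))
  list(m = m, Nm = input$N * m, N = input$N, R2 = r2, data = dat)
}

#' Summarize a neutral-model fit
#'
#' @param fit result of [ncm_fit()].
#' @return data.frame with one row: `m`, `Nm`, `R2`, `n_otus`, `n_above`,
#'   `n_neutral`, `n_below`.
#' @export
ncm_report <- function(fit) {
  tab <- table(factor(fit$data$partition,
                      levels = c("above", "neutral", "below")))
  data.frame(m = fit$m, Nm = fit$Nm, R2 = fit$R2,
             n_otus = nrow(fit$data),
             n_above = as.integer(tab["above"]),
             n_neutral = as.integer(tab["neutral"]),
             n_below = as.integer(tab["below"]),
             row.names = NULL)
}
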
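# Comparator methods: dictionary matching on R^2, and the analytical vessel
# size index from MRI relaxation-rate changes (VSI_MRI) or from the radius
# distribution itself (VSI_Histo).

#' Signal dictionary for fingerprint matching
#'
#' @param signals M x 18 matrix of dictionary signal ratios (typically the
#'   training partition).
#' @param cbv_labels M CBV fractions paired with the entries.
#' @param vsd_labels M x 40 VSD matrix paired with the entries.
#' @return A `signal_dictionary`.
#' @export
signal_dictionary <- function(signals, cbv_labels, vsd_labels) {
  signals <- as.matrix(signals)
  stopifnot(nrow(signals) >= 1, nrow(signals) == length(cbv_labels),
            nrow(signals) == nrow(vsd_labels))
  structure(list(signals = signals, cbv_labels = cbv_labels,
                 vsd_labels = as.matrix(vsd_labels)),
            class = "signal_dictionary")
}

#' Dictionary matching by maximum coefficient of determination
#'
#' Each query is compared to every dictionary entry by
#' `R^2 = 1 - SS_res / SS_tot` (residuals of the entry against the query,
#' total sum of squares about the query mean); the labels of the entry with
#' the highest R^2 are returned, ties broken by the lowest entry index.  A
#' zero-variance query has no defined R^2; matching falls back to the
#' minimum residual sum of squares with a warning.
#'
#' @param query an 18-vector, or N x 18 matrix of queries.
#' @param dict a [signal_dictionary()].
#' @return List with `cbv`, `vsd` (N x 40), `best_r2` and `index`.
#' @export
dictionary_match <- function(query, dict) {
  stopifnot(inherits(dict, "signal_dictionary"))
  Q <- if (is.null(dim(query))) matrix(query, nrow = 1) else as.matrix(query)
  E <- dict$signals
  n <- nrow(Q)
  idx <- integer(n)
  r2 <- numeric(n)
  for (i in seq_len(n)) {
    q <- Q[i, ]
    ss_tot <- sum((q - mean(q))^2)
    ss_res <- colSums((t(E) - q)^2)
    if (ss_tot == 0) {
      warning("zero-variance query: falling back to minimum sum of squares")
      j <- which.min(ss_res)
      idx[i] <- j
      r2[i] <- NA_real_
    } else {
      r2_all <- 1 - ss_res / ss_tot
      j <- which.max(r2_all) # which.max takes the first (lowest index) tie
      idx[i] <- j
      r2[i] <- r2_all[j]
    }
  }
  list(cbv = dict$cbv_labels[idx],
       vsd = dict$vsd_labels[idx, , drop = FALSE],
       best_r2 = r2, index = idx)
}

#' Parameters of the analytical vessel size index
#'
#' The printed value of the gyromagnetic constant in the source table
#' (4.258e-7 s^-1 T^-1) is dimensionally implausible for the formula; the
#' default is the proton gyromagnetic ratio in rad s^-1 T^-1, with the
#' alternative available by passing it explicitly.
#'
#' @param ADC apparent diffusion coefficient in um^2/ms.
#' @param gamma gyromagnetic ratio in rad s^-1 T^-1.
#' @param B0 field strength in Tesla.
#' @param delta_chi susceptibility difference (dimensionless).
#' @return A `vsi_params` list.
#' @export
vsi_params <- function(ADC = 1, gamma = GAMMA_PROTON, B0 = 3,
                       delta_chi = 1e-6) {
  stopifnot(ADC > 0, gamma > 0, B0 > 0, delta_chi > 0)
  structure(list(ADC = ADC, gamma = gamma, B0 = B0, delta_chi = delta_chi),
            class = "vsi_params")
}

#' MRI vessel size index from relaxation-rate changes
#'
#' `VSI_MRI = 0.425 * (ADC / (gamma * delta_chi * B0))^(1/2) *
#' (dR2* / dR2)^(3/2)`, evaluated in SI and returned in micrometre.
#'
#' @param dR2star,dR2 contrast-induced relaxation-rate changes in 1/s
#'   (`dR2` must be positive; a non-positive value yields `NA` with a
#'   warning, flagging the voxel).
#' @param p a [vsi_params()].
#' @return VSI in um.
#' @export
vsi_mri <- function(dR2star, dR2, p = vsi_params()) {
  stopifnot(inherits(p, "vsi_params"))
  adc_si <- p$ADC * 1e-9 # um^2/ms -> m^2/s
  out <- ifelse(dR2 > 0,
                0.425 * sqrt(adc_si / (p$gamma * p$delta_chi * p$B0)) *
                  (dR2star / dR2)^1.5 * 1e6,
                NA_real_)
  if (anyNA(out)) warning("non-positive dR2: VSI undefined for some voxels")
  out
}

#' Histogram vessel size index from a vessel size distribution
#'
#' `VSI_Histo = [sum_i f_i * c_i^(-2/3)]^(-3/2)` with bin centres `c_i` and
#' `f` renormalized to unit sum (so the result is invariant to any rescaling
#' of the histogram).  A distribution concentrated at radius R returns R.
#'
#' @param vsd a `vsd_histogram` or a non-negative numeric vector (1-um bins
#'   starting at 0, centres `i + 0.5`).
#' @return VSI in um.
#' @export
vsi_histo <- function(vsd) {
  v <- if (inherits(vsd, "vsd_histogram")) vsd$values else as.numeric(vsd)
  centers <- if (inherits(vsd, "vsd_histogram")) vsd$bin_centers else
    seq_along(v) - 0.5
  s <- sum(v)
  if (s <= 0) stop("VSI undefined for an all-zero VSD")
  f <- v / s
  sum(f * centers^(-2 / 3))^(-3 / 2)
}
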
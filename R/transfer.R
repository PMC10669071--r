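# Transfer functions, coherences and noise-source contributions derived
# from a freq_model. Directions are always named, never indexed:
# "sbp->ibi" is the baroreflex (feedback) arm in ms/mmHg, "ibi->sbp" the
# mechanical (feedforward) arm in mmHg/ms.

.direction_index <- function(direction) .path_index(direction)

.tf_units <- function(direction) {
  if (direction == "sbp->ibi") "ms/mmHg" else "mmHg/ms"
}

.new_tf <- function(freqs, values, kind, direction) {
  structure(list(freqs = freqs, values = values, gain = Mod(values),
                 phase = Arg(values), kind = kind, direction = direction,
                 units = .tf_units(direction)),
            class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("transfer_function (%s, %s, %s): %d frequencies\n",
              x$kind, x$direction, x$units, length(x$freqs)))
  invisible(x)
}

#' Closed-loop transfer function of one arm of the loop
#'
#' For direction `"sbp->ibi"` (baroreflex) returns
#' `alpha_c(f) = A[ibi,sbp](f) / (1 - A[ibi,ibi](f))`: the coupling entry
#' of the chosen arm over one minus the target channel's autoregressive
#' entry. The biased variant (`corrected = FALSE`) uses the lagged-only
#' coefficients; the corrected variant requires a model after
#' [extract_instantaneous()], whose zero-lag term participates in `A(f)`.
#'
#' @param fm a [to_frequency_domain()] model (extracted, for
#'   `corrected = TRUE`).
#' @param direction `"sbp->ibi"` (default) or `"ibi->sbp"`.
#' @param corrected use the zero-lag-corrected coefficients (default TRUE
#'   when extraction has been performed).
#' @return A `transfer_function` (fields `freqs`, `values`, `gain`,
#'   `phase`, `units`).
#' @export
closed_loop_transfer <- function(fm, direction = "sbp->ibi",
                                 corrected = fm$zero_lag_path != "none") {
  stopifnot(inherits(fm, "freq_model"))
  idx <- .direction_index(direction)
  if (corrected && fm$zero_lag_path == "none") {
    stop("corrected transfer requires extract_instantaneous() first",
         call. = FALSE)
  }
  A <- if (corrected) {
    fm$A
  } else {
    # biased variant: lagged coefficients only, regardless of extraction
    if (fm$zero_lag_path == "none") fm$A else {
      .freq_A(lapply(seq_len(fm$p), function(k) fm$D %*% fm$coeffs[[k]]),
              matrix(0, 2, 2), fm$freqs, fm$fs)
    }
  }
  num <- A[idx["target"], idx["source"], ]
  den <- 1 - A[idx["target"], idx["target"], ]
  if (any(Mod(den) < 1e-12)) {
    stop("transfer denominator vanishes at some frequency", call. = FALSE)
  }
  .new_tf(fm$freqs, num / den,
          kind = if (corrected) "closed_corrected" else "closed_biased",
          direction = direction)
}

#' Open-loop transfer function (classical BRS estimators)
#'
#' `type_I` is the classical cross-spectral ratio
#' `alpha_o(f) = S[sbp,ibi](f) / S[sbp,sbp](f)` evaluated on the parametric
#' cross-spectral matrix, exact when the loop is truly open. `type_II` is
#' the noise-path ratio `H'[ibi,sbp](f) / H'[sbp,sbp](f)`, a documented
#' formula choice validated through the ordering property (type I >=
#' type II >= corrected closed-loop, band-averaged); it requires a model
#' after extraction. Both are reported in ms/mmHg for the baroreflex
#' direction.
#'
#' @param fm a `freq_model`.
#' @param variant `"type_I"` (default) or `"type_II"`.
#' @return A `transfer_function`.
#' @export
open_loop_transfer <- function(fm, variant = c("type_I", "type_II")) {
  stopifnot(inherits(fm, "freq_model"))
  variant <- match.arg(variant)
  if (variant == "type_I") {
    s22 <- Re(fm$S[2, 2, ])
    if (any(s22 < 1e-15)) {
      stop("SBP auto-spectrum vanishes at some frequency", call. = FALSE)
    }
    vals <- fm$S[2, 1, ] / s22        # cross(SBP, IBI) / auto(SBP)
    .new_tf(fm$freqs, vals, kind = "open_type_I", direction = "sbp->ibi")
  } else {
    if (fm$zero_lag_path == "none") {
      stop("type_II requires extract_instantaneous() first", call. = FALSE)
    }
    h22 <- fm$H[2, 2, ]
    if (any(Mod(h22) < 1e-15)) {
      stop("SBP own-noise transfer vanishes at some frequency",
           call. = FALSE)
    }
    .new_tf(fm$freqs, fm$H[1, 2, ] / h22, kind = "open_type_II",
            direction = "sbp->ibi")
  }
}

.coherence_of_S <- function(S, freqs, kind, direction = NA_character_) {
  s11 <- Re(S[1, 1, ])
  s22 <- Re(S[2, 2, ])
  if (any(s11 <= 0) || any(s22 <= 0)) {
    stop("auto-spectrum vanishes; coherence undefined", call. = FALSE)
  }
  coh <- Mod(S[1, 2, ])^2 / (s11 * s22)
  coh <- pmin(pmax(coh, 0), 1)
  structure(list(freqs = freqs, values = coh, kind = kind,
                 direction = direction),
            class = "coherence_function")
}

#' @export
print.coherence_function <- function(x, ...) {
  cat(sprintf("coherence_function (%s%s): %d frequencies, mean %.3f\n",
              x$kind,
              if (!is.na(x$direction)) paste0(", ", x$direction) else "",
              length(x$freqs), mean(x$values)))
  invisible(x)
}

#' Squared spectral coherence
#'
#' `coh2(f) = |S[ibi,sbp](f)|^2 / (S[ibi,ibi](f) S[sbp,sbp](f))`, clipped
#' to `[0, 1]`.
#'
#' @param fm a `freq_model`.
#' @return A `coherence_function` with values in `[0, 1]`.
#' @export
spectral_coherence <- function(fm) {
  stopifnot(inherits(fm, "freq_model"))
  .coherence_of_S(fm$S, fm$freqs, "ordinary")
}

#' Causal (directed) squared coherence
#'
#' Coherence of the cross-spectral matrix rebuilt after zeroing the noise
#' path that carries the opposite direction: for `direction = "sbp->ibi"`
#' the entry `H'[sbp, ibi]` (IBI noise into SBP) is set to zero, so the
#' coherence that remains is attributable to the SBP-to-IBI coupling
#' alone. Requires a model after [extract_instantaneous()] (diagonal noise
#' covariance).
#'
#' @param fm an extracted `freq_model`.
#' @param direction `"sbp->ibi"` or `"ibi->sbp"`.
#' @return A `coherence_function`.
#' @export
causal_coherence <- function(fm, direction = "sbp->ibi") {
  stopifnot(inherits(fm, "freq_model"))
  if (fm$zero_lag_path == "none") {
    stop("causal coherence requires extract_instantaneous() first",
         call. = FALSE)
  }
  idx <- .direction_index(direction)
  # suppress the opposite arm: the entry feeding the *target-of-opposite*
  # (= this direction's source channel) with the source-of-opposite noise
  H0 <- fm$H
  H0[idx["source"], idx["target"], ] <- 0 + 0i
  nf <- length(fm$freqs)
  S <- array(0 + 0i, dim = dim(H0))
  for (i in seq_len(nf)) {
    S[, , i] <- H0[, , i] %*% fm$sigma %*% Conj(t(H0[, , i]))
  }
  .coherence_of_S(S, fm$freqs, "causal", direction)
}

#' Noise-source contribution spectra
#'
#' For each channel, the percentage of its spectrum explained by each of
#' the two diagonalized innovation sources:
#' `100 * |H'[i,j](f)|^2 sigma_j^2 / S[i,i](f)`. Under a diagonal noise
#' covariance the two contributions sum to 100 at every frequency. A large
#' foreign-noise share indicates a strong causal drive from the other
#' channel.
#'
#' @param fm an extracted `freq_model`.
#' @return A list with `freqs` and a 2x2xn array `percent` where
#'   `percent[i, j, ]` is the contribution of source `j` to channel `i`
#'   (channels ordered IBI, SBP).
#' @export
noise_contribution <- function(fm) {
  stopifnot(inherits(fm, "freq_model"))
  if (fm$zero_lag_path == "none") {
    stop("noise contributions require extract_instantaneous() first",
         call. = FALSE)
  }
  nf <- length(fm$freqs)
  pc <- array(NA_real_, dim = c(2, 2, nf),
              dimnames = list(c("ibi", "sbp"), c("ibi_noise", "sbp_noise"),
                              NULL))
  s2 <- diag(fm$sigma)
  for (i in 1:2) {
    Sii <- Re(fm$S[i, i, ])
    if (any(Sii <= 0)) stop("vanishing auto-spectrum", call. = FALSE)
    for (j in 1:2) {
      pc[i, j, ] <- 100 * Mod(fm$H[i, j, ])^2 * s2[j] / Sii
    }
  }
  list(freqs = fm$freqs, percent = pc)
}
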
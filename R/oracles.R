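# Reference oracles: deliberately simple, self-contained implementations
# used to cross-check the compiled engine.  They intentionally share no code
# with the kernel (all physics re-derived inline, R RNG instead of the
# kernel's counter-based generator).

#' Scalar single-photon reference walker
#'
#' A one-photon-at-a-time random walk implementing the same physics as the
#' transport engine (total-rate stepping, Henyey-Greenstein scattering,
#' Fresnel surface, weight absorption, roulette) in plain R with no
#' vectorization or shared code.  Used as ground truth for engine
#' equivalence on small problems.
#'
#' @param model A [skin_model()].
#' @param config A [run_config()]; keep `n_photons` small (<= 1e5).
#' @param ring_edges Detector bin edges (mm), radial binning.
#' @param lib A [chromophore_library()].
#' @param matched_boundaries Logical, as in [run_transport()].
#' @return A data.frame of class `oracle_result`, one row per detector bin:
#'   weighted mean detected path `estimate`, its `standard_error`,
#'   detected count `n`, detected weight, and the method tag.
#' @export
scalar_walker <- function(model, config, ring_edges = detector_edges(),
                          lib = chromophore_library(),
                          matched_boundaries = FALSE) {
  stopifnot(inherits(model, "skin_model"), inherits(config, "run_config"))
  op <- model_optical_properties(model, config$wavelength, lib)
  nlay <- nrow(op)
  zb <- cumsum(c(0, op$thickness))
  n_amb <- model$n_ambient
  K <- length(ring_edges) - 1
  wsum <- wp <- wp2 <- numeric(K)
  ndet <- integer(K)
  fres <- function(n1, n2, ci) {
    st <- n1 / n2 * sqrt(max(0, 1 - ci^2))
    if (st >= 1) return(1)
    ct <- sqrt(1 - st^2)
    rs <- (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct)
    rp <- (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci)
    (rs^2 + rp^2) / 2
  }
  r_sp <- if (matched_boundaries) 0 else fres(n_amb, op$n[1], 1)
  set.seed(config$seed + config$stream)
  for (ph in seq_len(config$n_photons)) {
    x <- y <- z <- 0; ux <- uy <- 0; uz <- 1
    w <- 1 - r_sp; path <- 0; lay <- 1; alive <- TRUE
    while (alive) {
      s_opt <- -log(stats::runif(1))   # optical depth to the next event
      moving <- TRUE
      while (moving) {
        mut <- op$mua[lay] + op$mus[lay]
        s <- if (mut > 0) s_opt / mut else 2 * config$max_path
        db <- if (uz > 0) (zb[lay + 1] - z) / uz
              else if (uz < 0) (zb[lay] - z) / uz else Inf
        step <- min(s, db)
        if (path + step > config$max_path) {
          alive <- FALSE; break
        }
        x <- x + ux * step; y <- y + uy * step; z <- z + uz * step
        path <- path + step
        if (s < db) { moving <- FALSE; break }
        s_opt <- s_opt - db * mut
        if (uz < 0 && lay == 1) {
          ci <- -uz
          R <- if (matched_boundaries) 0 else fres(op$n[1], n_amb, ci)
          if (stats::runif(1) <= R) { uz <- -uz; z <- 0 }
          else {
            r <- sqrt(x^2 + y^2)
            k <- findInterval(r, ring_edges)
            if (k >= 1 && k <= K && r < ring_edges[K + 1]) {
              ndet[k] <- ndet[k] + 1L
              wsum[k] <- wsum[k] + w
              wp[k] <- wp[k] + w * path
              wp2[k] <- wp2[k] + w * path^2
            }
            alive <- FALSE
          }
          if (!alive) break
        } else if (uz > 0 && lay == nlay) {
          alive <- FALSE; break
        } else {
          nxt <- if (uz > 0) lay + 1 else lay - 1
          if (matched_boundaries || op$n[lay] == op$n[nxt]) lay <- nxt
          else {
            ci <- abs(uz)
            if (stats::runif(1) <= fres(op$n[lay], op$n[nxt], ci)) uz <- -uz
            else {
              ratio <- op$n[lay] / op$n[nxt]
              ct <- sqrt(max(0, 1 - ratio^2 * (1 - ci^2)))
              d <- c(ux * ratio, uy * ratio, sign(uz) * ct)
              d <- d / sqrt(sum(d^2))
              ux <- d[1]; uy <- d[2]; uz <- d[3]
              lay <- nxt
            }
          }
        }
      }
      if (!alive) break
      dw <- w * op$mua[lay] / (op$mua[lay] + op$mus[lay])
      w <- w - dw
      if (w <= 0) break
      g <- op$g[lay]
      u1 <- stats::runif(1)
      ct <- if (abs(g) < 1e-12) 2 * u1 - 1
            else {
              tt <- (1 - g^2) / (1 - g + 2 * g * u1)
              max(-1, min(1, (1 + g^2 - tt^2) / (2 * g)))
            }
      st <- sqrt(max(0, 1 - ct^2))
      phi <- 2 * pi * stats::runif(1)
      if (abs(uz) > 0.99999) {
        ux <- st * cos(phi); uy <- st * sin(phi); uz <- ct * sign(uz)
      } else {
        den <- sqrt(1 - uz^2)
        nx <- st * (ux * uz * cos(phi) - uy * sin(phi)) / den + ux * ct
        ny <- st * (uy * uz * cos(phi) + ux * sin(phi)) / den + uy * ct
        nz <- -den * st * cos(phi) + uz * ct
        nn <- sqrt(nx^2 + ny^2 + nz^2)
        ux <- nx / nn; uy <- ny / nn; uz <- nz / nn
      }
      if (config$roulette && w < config$roulette_threshold) {
        if (stats::runif(1) <= config$roulette_survival)
          w <- w / config$roulette_survival
        else break
      }
    }
  }
  est <- ifelse(wsum > 0, wp / wsum, NA_real_)
  # weighted variance of the path -> SE of the weighted mean
  varw <- ifelse(wsum > 0, pmax(0, wp2 / wsum - est^2), NA_real_)
  se <- ifelse(ndet > 1, sqrt(varw / ndet), NA_real_)
  structure(data.frame(
    sds = (ring_edges[-1] + ring_edges[-length(ring_edges)]) / 2,
    estimate = est, standard_error = se, n = ndet,
    detected_weight = wsum,
    method = "scalar_walker", stringsAsFactors = FALSE),
    class = c("oracle_result", "data.frame"))
}

#' Diffusion-theory DPF for a homogeneous semi-infinite medium
#'
#' Steady-state closed form
#' `DPF = (1/2) sqrt(3 mus' / mua) * (1 - 1 / (1 + d sqrt(3 mua mus')))`,
#' valid in the diffusive regime (`mus' >> mua`, separations of several
#' transport mean free paths).  Used as a large-separation sanity oracle;
#' diffusion theory itself is only accurate to ~10-15% near sources and
#' boundaries, which sets the comparison tolerance.
#'
#' @param mua Absorption coefficient, 1/mm, `> 0`.
#' @param mus_reduced Reduced scattering coefficient `mus (1 - g)`, 1/mm,
#'   `> 0`.
#' @param d Source-detector separation, mm.
#' @return DPF value.
#' @export
diffusion_dpf <- function(mua, mus_reduced, d) {
  if (any(mua <= 0) || any(mus_reduced <= 0))
    stop("mua and mus_reduced must be strictly positive", call. = FALSE)
  0.5 * sqrt(3 * mus_reduced / mua) *
    (1 - 1 / (1 + d * sqrt(3 * mua * mus_reduced)))
}

#' Mean scattering cosine of the Henyey-Greenstein density by quadrature
#'
#' Numerically integrates `cos(theta) p_HG(cos theta)` over `[-1, 1]`; the
#' closed-form answer is the anisotropy `g` itself, so this provides an
#' independent check of the sampled single-scattering statistics.
#'
#' @param g Anisotropy factor, `|g| < 1`.
#' @return Mean cosine (numerically equal to `g`).
#' @export
hg_mean_cos_numeric <- function(g) {
  if (abs(g) >= 1) stop("|g| must be < 1", call. = FALSE)
  dens <- function(mu) 0.5 * (1 - g^2) / (1 + g^2 - 2 * g * mu)^1.5
  stats::integrate(function(mu) mu * dens(mu), -1, 1,
                   rel.tol = 1e-10)$value
}
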
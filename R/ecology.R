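#' Ecological (birth-death-competition) parameters
#'
#' Within each site, resources are distributed continuously over phenotype
#' space: the carrying-capacity function is Gaussian with maximum `K_star` at
#' the site's environmental optimum and standard deviation `sigma_K`.
#' Competition between individuals is frequency-dependent with a Gaussian
#' kernel of standard deviation `sigma_C` and maximum 1 for identical
#' phenotypes. Selection within a site is disruptive only when
#' `sigma_K > sigma_C`, which the constructor enforces.
#'
#' @param r Per-capita birth rate; one generation is `1/r` model time.
#' @param K_star Maximal local carrying capacity (individuals).
#' @param sigma_K Carrying-capacity width (trait units).
#' @param sigma_C Competition-kernel width (trait units).
#' @param m Newborn dispersal probability (used by the `"stay_move"`
#'   dispersal rule; the default `"island"` rule spreads each newborn
#'   uniformly over the natal site and its open-border neighbors).
#' @return A list of class `"ecology_params"`.
#' @export
ecology_params <- function(r = 1.0, K_star = 150, sigma_K = 1.0,
                           sigma_C = 0.4, m = 1.0) {
  stopifnot(r > 0, K_star > 0, sigma_K > 0, sigma_C > 0, m >= 0, m <= 1)
  if (sigma_K <= sigma_C)
    stop("disruptive selection requires sigma_K > sigma_C")
  structure(list(r = r, K_star = K_star, sigma_K = sigma_K,
                 sigma_C = sigma_C, m = m),
            class = "ecology_params")
}

#' Local carrying capacity
#'
#' `K(z) = K_star * exp(-||z - z*||^2 / (2 sigma_K^2))`: the number of
#' individuals of phenotype `z` that the site with environmental optimum `z*`
#' can sustain.
#'
#' @param z Length-2 phenotype `(x1, x2)`.
#' @param optimum Length-2 site optimum `(x1*, x2*)`.
#' @param K_star,sigma_K See [ecology_params()].
#' @return Carrying capacity (individuals).
#' @export
carrying_capacity <- function(z, optimum, K_star = 150, sigma_K = 1.0) {
  K_star * exp(-sum((z - optimum)^2) / (2 * sigma_K^2))
}

#' Competition kernel
#'
#' `C(z_i, z_j) = exp(-||z_i - z_j||^2 / (2 sigma_C^2))`: symmetric Gaussian
#' similarity in phenotype space, equal to 1 for identical phenotypes.
#'
#' @param z_i,z_j Length-2 phenotypes.
#' @param sigma_C Competition width (trait units).
#' @return Competition coefficient in `(0, 1]`.
#' @export
competition_kernel <- function(z_i, z_j, sigma_C = 0.4) {
  exp(-sum((z_i - z_j)^2) / (2 * sigma_C^2))
}

#' Individual death rate under local competition
#'
#' `d(z_i) = r / K(z_i) * sum_j C(z_i, z_j)` over the co-residents `j != i`
#' of the same geographical site; competition is strictly within-site. A lone
#' individual has death rate zero.
#'
#' @param z Length-2 phenotype of the focal individual.
#' @param others Matrix (or data.frame) of co-resident phenotypes with two
#'   columns `(x1, x2)`; must not include the focal individual.
#' @param optimum Length-2 site optimum.
#' @param eco An [ecology_params()] object.
#' @return Death rate (per model time).
#' @export
death_rate <- function(z, others, optimum, eco = ecology_params()) {
  if (NROW(others) == 0L) return(0)
  others <- as.matrix(others)
  d2 <- (others[, 1] - z[1])^2 + (others[, 2] - z[2])^2
  comp <- sum(exp(-d2 / (2 * eco$sigma_C^2)))
  eco$r * comp / carrying_capacity(z, optimum, eco$K_star, eco$sigma_K)
}

#' Newborn dispersal
#'
#' Under the default `"island"` rule the newborn lands uniformly on the natal
#' site or any site connected to it by an open border (each of the `k + 1`
#' targets with probability `1/(k + 1)`). Under the `"stay_move"` rule it
#' stays home with probability `1 - m` and otherwise moves to a uniform draw
#' among the open-border neighbors (staying if there are none).
#'
#' @param natal_site Natal site index.
#' @param landscape A `"landscape"` object.
#' @param m Dispersal probability (only used by `"stay_move"`).
#' @param mode `"island"` or `"stay_move"`.
#' @return The site index where the newborn establishes.
#' @export
disperse_newborn <- function(natal_site, landscape, m = 1.0,
                             mode = c("island", "stay_move")) {
  mode <- match.arg(mode)
  nb <- open_neighbors(landscape, natal_site)
  if (length(nb) == 0L) return(natal_site)
  if (mode == "island") {
    targets <- c(natal_site, nb)
    return(targets[sample.int(length(targets), 1L)])
  }
  if (stats::runif(1) >= m) return(natal_site)
  nb[sample.int(length(nb), 1L)]
}
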
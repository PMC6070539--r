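#' Mating-rule parameters
#'
#' @param c_am Scaling constant of the Gaussian mating kernel.
#' @param AMT Assortative mating threshold: mating probability (evaluated on
#'   subpopulation mean traits) strictly below which two subpopulations are
#'   prezygotically isolated. Default 0.01.
#' @param GIT Genetic incompatibility threshold: number of divergent
#'   incompatibility loci strictly above which two individuals (or
#'   subpopulations) cannot interbreed. Default 15.
#' @param max_tries Maximum number of potential mates tried per reproduction
#'   event. Default 50.
#' @return A list of class `"mating_params"`.
#' @export
mating_params <- function(c_am = 1.0, AMT = 0.01, GIT = 15, max_tries = 50L) {
  stopifnot(c_am > 0, AMT > 0, AMT < 1, GIT >= 1, max_tries >= 1)
  structure(list(c_am = c_am, AMT = AMT, GIT = GIT,
                 max_tries = as.integer(max_tries)),
            class = "mating_params")
}

#' Mating probability between two phenotypes
#'
#' The probability `Q(i, j)` that individuals `i` and `j` mate, given their
#' ecological phenotypes `z = (x1, x2)` and choosiness traits. The rule uses
#' the choosiness value `a` of the choosier individual (larger `|a|`). For
#' `a > 0` (assortative mating),
#' `Q = (1 - exp(-a^2)/2) * exp(-||z_i - z_j||^2 / (2 / (a^2 c_am))^2)`;
#' for `a = 0` the individual has no preference and `Q = 0.5`; for `a < 0`
#' (disassortative mating) `Q` is the complement of the `a > 0` branch. `Q`
#' is continuous in `a`, symmetric in the pair, and increasingly selective as
#' `|a|` grows.
#'
#' @param z_i,z_j Length-2 numeric ecological phenotypes `(x1, x2)`.
#' @param a_i,a_j Choosiness trait values.
#' @param c_am Kernel scaling constant.
#' @return A probability in `[0, 1]`.
#' @examples
#' mating_probability(c(0, 0), 0, c(5, 5), 0)  # no preference: 0.5
#' mating_probability(c(0, 0), 1, c(0, 0), 0)  # identical phenotypes: ~0.816
#' @export
mating_probability <- function(z_i, a_i, z_j, a_j, c_am = 1.0) {
  a <- if (abs(a_i) > abs(a_j)) a_i
       else if (abs(a_j) > abs(a_i)) a_j
       else max(a_i, a_j)  # |a_i| == |a_j|: deterministic, symmetric tie rule
  if (a == 0) return(0.5)
  d2 <- sum((z_i - z_j)^2)
  q_pos <- (1 - 0.5 * exp(-a^2)) * exp(-d2 / (2 / (a^2 * c_am))^2)
  if (a > 0) q_pos else 1 - q_pos
}

#' Can two individuals mate?
#'
#' Postzygotic gate first: if the incompatibility distance between the two
#' individuals strictly exceeds `GIT` they never mate. Otherwise mating
#' succeeds with probability `Q(i, j)` (a Bernoulli draw).
#'
#' @param i,j `"individual"` objects of opposite sex in the same site.
#' @param params A [mating_params()] object.
#' @return Logical.
#' @export
individuals_can_mate <- function(i, j, params) {
  if (incompat_distance(i, j) > params$GIT) return(FALSE)
  q <- mating_probability(c(i$x1, i$x2), i$a, c(j$x1, j$x2), j$a, params$c_am)
  stats::runif(1) < q
}

#' Mate search within a site
#'
#' Draws potential mates uniformly at random (with replacement) among the
#' opposite-sex residents of the focal individual's site; the first draw that
#' passes [individuals_can_mate()] is returned. The search gives up after
#' `max_tries` draws, or immediately if no opposite-sex resident exists —
#' a failed search consumes the reproduction event.
#'
#' @param focal The reproducing `"individual"`.
#' @param site_members List of `"individual"`s inhabiting the focal site
#'   (may include `focal`).
#' @param params A [mating_params()] object.
#' @return The chosen mate, or `NULL` if the search failed.
#' @export
select_mate <- function(focal, site_members, params) {
  opp <- Filter(function(x) x$sex != focal$sex, site_members)
  if (length(opp) == 0L) return(NULL)
  for (try in seq_len(params$max_tries)) {
    cand <- opp[[sample.int(length(opp), 1L)]]
    if (individuals_can_mate(focal, cand, params)) return(cand)
  }
  NULL
}

#' Prezygotic isolation between two subpopulations
#'
#' Evaluates the mating function on the average phenotypic traits of the two
#' subpopulations (using the choosiness mean of the choosier subpopulation);
#' the pair is prezygotically isolated when this average cross-breeding
#' probability falls strictly below the assortative mating threshold `AMT`.
#'
#' @param A,B Subpopulation summaries: lists (or one-row data.frames) with
#'   fields `mean_x1`, `mean_x2`, `mean_a` (as produced by
#'   [cluster_subpopulations()]).
#' @param params A [mating_params()] object.
#' @return Logical: `TRUE` if the subpopulations are prezygotically isolated.
#' @export
prezygotic_isolated_subpops <- function(A, B, params) {
  q <- mating_probability(c(A$mean_x1, A$mean_x2), A$mean_a,
                          c(B$mean_x1, B$mean_x2), B$mean_a, params$c_am)
  q < params$AMT
}
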
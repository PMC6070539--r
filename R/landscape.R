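#' Build a gradient landscape
#'
#' Constructs an `n x n` grid of habitat sites whose two-dimensional
#' environmental optima `z* = (x1*, x2*)` follow a linear gradient: both
#' coordinates increase by `delta_x` between adjacent sites in either grid
#' direction, and the central site of an odd-sided grid has optimum `(0, 0)`.
#' Adjacent sites (rook adjacency) are separated by borders that can carry
#' geographic barriers; a barrier arises on an open border at rate `f` and
#' disappears from a closed border at rate `c` (per generation). Local
#' catastrophes strike each site at rate `cr` and wipe out all residents.
#'
#' @param n Integer grid side (`n >= 1`).
#' @param delta_x Optimum increment between adjacent sites, in trait units.
#' @param f Per-border rate at which a barrier arises (border closes).
#' @param c Per-border rate at which a barrier disappears (border opens).
#' @param cr Per-site local catastrophe rate.
#' @param borders_closed Initial border state; the default `FALSE` starts with
#'   every border open, so the founding species can spread over all sites.
#' @return An object of class `"landscape"`: a list with elements `n`,
#'   `sites` (data.frame: `site`, `row`, `col`, `x1_opt`, `x2_opt`),
#'   `borders` (data.frame: `border`, `site_a`, `site_b`, `closed`), and the
#'   rates `f`, `c`, `cr`.
#' @examples
#' L <- gradient_landscape(3, delta_x = 1)
#' subset(L$sites, x1_opt == 0 & x2_opt == 0)  # central site
#' nrow(L$borders)                             # 2 n (n - 1) = 12
#' @export
gradient_landscape <- function(n, delta_x = 1.0, f = 1e-3, c = 5e-5, cr = 0,
                               borders_closed = FALSE) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("'n' must be a single positive integer")
  if (delta_x <= 0) stop("'delta_x' must be > 0")
  center <- (n + 1) / 2  # integer for odd n; half-integer offset otherwise
  idx <- seq_len(n)
  grid <- expand.grid(row = idx, col = idx)
  sites <- data.frame(
    site = seq_len(n * n),
    row = grid$row, col = grid$col,
    x1_opt = (grid$col - center) * delta_x,
    x2_opt = (grid$row - center) * delta_x
  )
  new_landscape(n, sites, f, c, cr, borders_closed, delta_x = delta_x)
}

#' Build a randomized landscape
#'
#' Draws each site's optimum coordinates independently and uniformly on
#' `[-width/2, +width/2]`, breaking any correlation between geographic
#' proximity and ecological similarity. Used to test the robustness of
#' gradient-landscape results to the spatial arrangement of resources.
#'
#' @inheritParams gradient_landscape
#' @param width Width of the uniform distribution of optima (trait units);
#'   `width = 0` collapses all optima onto `(0, 0)`.
#' @return A `"landscape"` object; see [gradient_landscape()].
#' @export
random_landscape <- function(n, width, f = 1e-3, c = 5e-5, cr = 0,
                             borders_closed = FALSE) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("'n' must be a single positive integer")
  if (width < 0) stop("'width' must be >= 0")
  idx <- seq_len(n)
  grid <- expand.grid(row = idx, col = idx)
  sites <- data.frame(
    site = seq_len(n * n),
    row = grid$row, col = grid$col,
    x1_opt = stats::runif(n * n, -width / 2, width / 2),
    x2_opt = stats::runif(n * n, -width / 2, width / 2)
  )
  new_landscape(n, sites, f, c, cr, borders_closed, width = width)
}

# shared constructor: rook borders + validity
new_landscape <- function(n, sites, f, c_rate, cr, borders_closed, ...) {
  if (any(c(f, c_rate, cr) < 0)) stop("rates 'f', 'c', 'cr' must be >= 0")
  site_at <- function(row, col) (col - 1L) * n + row
  horiz <- if (n > 1) expand.grid(row = 1:n, col = 1:(n - 1)) else NULL
  vert  <- if (n > 1) expand.grid(row = 1:(n - 1), col = 1:n) else NULL
  a <- c(integer(0),
         if (!is.null(horiz)) site_at(horiz$row, horiz$col),
         if (!is.null(vert))  site_at(vert$row, vert$col))
  b <- c(integer(0),
         if (!is.null(horiz)) site_at(horiz$row, horiz$col + 1L),
         if (!is.null(vert))  site_at(vert$row + 1L, vert$col))
  borders <- data.frame(border = seq_along(a), site_a = a, site_b = b,
                        closed = rep(isTRUE(borders_closed), length(a)))
  stopifnot(nrow(borders) == 2 * n * (n - 1))
  structure(list(n = n, sites = sites, borders = borders,
                 f = f, c = c_rate, cr = cr, extra = list(...)),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d x %d sites, %d borders (%d closed)\n",
              x$n, x$n, nrow(x$borders), sum(x$borders$closed)))
  cat(sprintf("  barrier rates f = %g, c = %g; catastrophe rate cr = %g\n",
              x$f, x$c, x$cr))
  cat(sprintf("  pace = %g, isolation fraction = %s\n",
              landscape_pace(x$f, x$c),
              if (x$f > 0 || x$c > 0) format(isolation_fraction(x$f, x$c))
              else "NA"))
  invisible(x)
}

#' Pace of landscape dynamics
#'
#' The characteristic rate of a full barrier open/close cycle,
#' `1 / (1/f + 1/c)`: the inverse of the expected cycle duration of a single
#' border alternating between open (expected sojourn `1/f`) and closed
#' (expected sojourn `1/c`) states.
#'
#' @param f Rate at which a barrier arises on an open border.
#' @param c Rate at which a barrier disappears from a closed border.
#' @return The pace, per generation.
#' @examples
#' landscape_pace(1e-3, 5e-5)  # 4.76e-5, the default pace
#' @export
landscape_pace <- function(f, c) {
  if (any(f <= 0) || any(c <= 0)) stop("pace requires f > 0 and c > 0")
  1 / (1 / f + 1 / c)
}

#' Long-run fraction of time a border is closed
#'
#' Time in isolation `f / (f + c)`: the stationary probability that the
#' two-state barrier process on a single border is in the closed state.
#'
#' @inheritParams landscape_pace
#' @return Fraction in `[0, 1]`.
#' @examples
#' isolation_fraction(1e-3, 5e-5)  # ~0.952, the default isolation time
#' @export
isolation_fraction <- function(f, c) {
  if (any(f <= 0) || any(c <= 0)) stop("isolation fraction requires f > 0 and c > 0")
  f / (f + c)
}

#' Solve barrier rates from pace and isolation time
#'
#' Inverts the two summary statistics: given a pace `p = 1/(1/f + 1/c)` and an
#' isolation fraction `q = f/(f + c)`, returns the unique rates
#' `f = p / (1 - q)` and `c = p / q`. Used by factor sweeps that vary one
#' summary while holding the other constant.
#'
#' @param pace Pace of landscape dynamics (per generation), `> 0`.
#' @param isolation Long-run closed fraction, in `(0, 1)`.
#' @return Named list with `f` and `c`.
#' @export
barrier_rates <- function(pace, isolation) {
  if (pace <= 0) stop("'pace' must be > 0")
  if (isolation <= 0 || isolation >= 1) stop("'isolation' must be in (0, 1)")
  list(f = pace / (1 - isolation), c = pace / isolation)
}

#' Sites reachable through open borders
#'
#' @param landscape A `"landscape"` object.
#' @param site A site index.
#' @return Sorted integer vector: the maximal set of sites reachable from
#'   `site` via borders that currently carry no barrier (always contains
#'   `site` itself).
#' @export
connected_component <- function(landscape, site) {
  stopifnot(inherits(landscape, "landscape"))
  ns <- landscape$n^2
  site <- as.integer(site)
  if (site < 1L || site > ns) stop("invalid site index")
  open <- landscape$borders[!landscape$borders$closed, , drop = FALSE]
  # flood fill over the open-border adjacency
  member <- logical(ns)
  member[site] <- TRUE
  frontier <- site
  while (length(frontier)) {
    nb <- c(open$site_b[open$site_a %in% frontier],
            open$site_a[open$site_b %in% frontier])
    nb <- unique(nb[!member[nb]])
    member[nb] <- TRUE
    frontier <- nb
  }
  which(member)
}

#' Open neighbors of a site
#'
#' Sites adjacent to `site` whose shared border is currently open; the set a
#' newborn can disperse into.
#'
#' @inheritParams connected_component
#' @return Integer vector of site indices (possibly empty).
#' @export
open_neighbors <- function(landscape, site) {
  stopifnot(inherits(landscape, "landscape"))
  b <- landscape$borders
  b <- b[!b$closed & (b$site_a == site | b$site_b == site), , drop = FALSE]
  setdiff(c(b$site_a, b$site_b), site)
}

#' Remove all individuals struck by a local catastrophe
#'
#' A catastrophe causes the immediate extinction of every population present
#' in the impacted site; all other sites are untouched.
#'
#' @param community A data.frame of individuals with a `site` column (e.g. a
#'   simulation snapshot).
#' @param site The struck site index.
#' @return The community with all rows at `site` removed.
#' @export
apply_catastrophe <- function(community, site) {
  stopifnot(is.data.frame(community), "site" %in% names(community))
  community[community$site != site, , drop = FALSE]
}

#' Mean optimum distance between adjacent sites
#'
#' Average Euclidean phenotypic distance between the environmental optima of
#' all rook-adjacent site pairs; the degree of resource-distribution overlap
#' between neighboring sites.
#'
#' @param landscape A `"landscape"` object.
#' @return A single number, in trait units.
#' @export
adjacent_optima_distance <- function(landscape) {
  stopifnot(inherits(landscape, "landscape"))
  s <- landscape$sites
  b <- landscape$borders
  d <- sqrt((s$x1_opt[b$site_a] - s$x1_opt[b$site_b])^2 +
            (s$x2_opt[b$site_a] - s$x2_opt[b$site_b])^2)
  mean(d)
}

#' Write a landscape to tab-separated files
#'
#' Serializes the site table (`site`, `row`, `col`, `x1_opt`, `x2_opt`) and the
#' border-state table to `<stem>_sites.tsv` and `<stem>_borders.tsv`.
#'
#' @param landscape A `"landscape"` object.
#' @param stem Output path stem.
#' @return Invisibly, the two file paths.
#' @export
write_landscape <- function(landscape, stem) {
  stopifnot(inherits(landscape, "landscape"))
  fs <- paste0(stem, c("_sites.tsv", "_borders.tsv"))
  utils::write.table(landscape$sites, fs[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(landscape$borders, fs[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fs)
}
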
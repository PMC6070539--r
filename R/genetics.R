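#' Genetic architecture parameters
#'
#' Parameters of the polygenic trait architecture and of the infinite-sites
#' incompatibility loci. Each of the three traits — the two ecological traits
#' `x1`, `x2` and the choosiness trait `a` — is controlled by `L_k` unlinked
#' additive diploid loci with no environmental effect. A transmitted allele
#' mutates with probability `mu_k`; the mutant allelic value is drawn from a
#' normal distribution centered on the parental value with standard deviation
#' `s_k * sqrt(2 L_k)`, which yields a mutational variance of `s_k^2` at the
#' trait level regardless of the number of loci. Neutral incompatibility
#' mutations arise at rate `mu_n` per birth under an infinite-sites model:
#' every new mutation hits a previously untouched locus and gets a globally
#' unique identifier.
#'
#' @param L_x,L_a Number of loci for the ecological traits and for the
#'   choosiness trait (default 16 each).
#' @param mu_k Per-locus, per-transmitted-allele mutation probability for the
#'   quantitative traits.
#' @param s_x,s_a Trait-level mutational standard deviation for the ecological
#'   and choosiness traits (trait units).
#' @param mu_n Per-birth probability of acquiring a new incompatibility
#'   mutation.
#' @param init_sd Standard deviation of the zero-centered Gaussian from which
#'   founder allelic values are drawn (allele-level; see [founder_individual()]).
#' @return A list of class `"genetic_params"`.
#' @export
genetic_params <- function(L_x = 16L, L_a = 16L, mu_k = 1e-3,
                           s_x = 0.1, s_a = 0.2, mu_n = 1e-3,
                           init_sd = 0.1) {
  stopifnot(L_x >= 1, L_a >= 1, mu_k >= 0, mu_k <= 1, s_x >= 0, s_a >= 0,
            mu_n >= 0, mu_n <= 1, init_sd >= 0)
  structure(list(L = c(x1 = as.integer(L_x), x2 = as.integer(L_x),
                       a = as.integer(L_a)),
                 mu_k = mu_k, s = c(x1 = s_x, x2 = s_x, a = s_a),
                 mu_n = mu_n, init_sd = init_sd),
            class = "genetic_params")
}

#' Trait value of an additive multilocus genotype
#'
#' The trait is the sum of all `2 L_k` allelic values divided by
#' `sqrt(2 L_k)`. Under this normalization a single allelic mutation of
#' standard deviation `s_k * sqrt(2 L_k)` perturbs the trait with variance
#' exactly `s_k^2`, independent of the number of loci.
#'
#' @param alleles Numeric matrix of allelic values, `L_k` rows (loci) by 2
#'   columns (the two homologous copies).
#' @return The trait value (trait units).
#' @export
trait_value <- function(alleles) {
  alleles <- as.matrix(alleles)
  sum(alleles) / sqrt(2 * nrow(alleles))
}

#' Create an individual
#'
#' Assembles an individual from its genotype; the phenotype cache is computed
#' from the allele matrices with [trait_value()].
#'
#' @param alleles Named list of three allele matrices (`x1`, `x2`, `a`), each
#'   `L_k` rows by 2 columns.
#' @param muts Integer vector of incompatibility-mutation identifiers; an
#'   identifier listed twice marks a homozygous carrier (diploid dosage 2).
#' @param sex `"F"` or `"M"`.
#' @param site Site index.
#' @param id Optional individual id.
#' @param parents Optional length-2 vector of parent ids.
#' @return A list of class `"individual"` with cached `x1`, `x2`, `a`.
#' @export
individual <- function(alleles, muts = integer(), sex = "F", site = 1L,
                       id = NA_integer_, parents = c(NA_integer_, NA_integer_)) {
  stopifnot(is.list(alleles), all(c("x1", "x2", "a") %in% names(alleles)),
            sex %in% c("F", "M"))
  muts <- sort(as.integer(muts))
  if (any(tabulate(factor(muts)) > 2))
    stop("an incompatibility locus cannot carry more than 2 allele copies")
  structure(list(id = id, sex = sex, site = as.integer(site),
                 alleles = alleles, muts = muts,
                 x1 = trait_value(alleles$x1),
                 x2 = trait_value(alleles$x2),
                 a  = trait_value(alleles$a),
                 parents = parents),
            class = "individual")
}

#' @export
print.individual <- function(x, ...) {
  cat(sprintf(
    "<individual> id %s, sex %s, site %d | z = (%.3f, %.3f), a = %.3f, %d incompatibility mutation(s)\n",
    format(x$id), x$sex, x$site, x$x1, x$x2, x$a, length(x$muts)))
  invisible(x)
}

#' Draw a founder individual
#'
#' Founders have every allelic value drawn independently from a Gaussian
#' centered at zero with standard deviation `init_sd`, and carry no
#' incompatibility mutations; the founding species therefore sits near the
#' central environmental optimum `(0, 0)`.
#'
#' @param params A [genetic_params()] object.
#' @param sex,site,id Passed to [individual()].
#' @return An `"individual"`.
#' @export
founder_individual <- function(params, sex = "F", site = 1L, id = NA_integer_) {
  al <- lapply(params$L, function(L)
    matrix(stats::rnorm(2 * L, 0, params$init_sd), nrow = L, ncol = 2))
  names(al) <- names(params$L)
  individual(al, integer(), sex, site, id)
}

#' Sexual reproduction with segregation and mutation
#'
#' Builds an offspring from two parents. For every quantitative-trait locus
#' one allele is drawn uniformly from each parent's two homologous copies
#' (free recombination / independent segregation); each transmitted allele
#' then mutates with probability `mu_k`, adding a Normal(0, `(s_k sqrt(2
#' L_k))^2`) deviate. Incompatibility loci segregate Mendelian-style on the
#' diploid dosage: a parent carrying `g` copies (1 heterozygous, 2
#' homozygous) of a mutation transmits one copy with probability `g/2`
#' independently per locus — so a heterozygous parent transmits each of its
#' mutations with probability 1/2, and fixation of derived alleles is
#' possible. With probability `mu_n` the offspring acquires one brand-new
#' heterozygous incompatibility mutation (infinite sites). Sex is assigned F
#' or M with probability 1/2 each (balanced sex ratio).
#'
#' @param mother,father Parents: `"individual"` objects of opposite sex
#'   inhabiting the same site.
#' @param params A [genetic_params()] object.
#' @param new_mut_id Identifier to assign if a new incompatibility mutation
#'   arises; required when `mu_n > 0`.
#' @param id Offspring id.
#' @return An `"individual"` at the mother's site.
#' @export
make_offspring <- function(mother, father, params, new_mut_id = NULL,
                           id = NA_integer_) {
  if (mother$sex == father$sex) stop("parents must be of opposite sex")
  if (mother$site != father$site) stop("parents must inhabit the same site")
  traits <- names(params$L)
  al <- vector("list", length(traits))
  names(al) <- traits
  for (k in traits) {
    L <- params$L[[k]]
    from_m <- mother$alleles[[k]][cbind(seq_len(L), sample.int(2, L, replace = TRUE))]
    from_f <- father$alleles[[k]][cbind(seq_len(L), sample.int(2, L, replace = TRUE))]
    gam <- unname(cbind(from_m, from_f))
    hit <- matrix(stats::runif(2 * L) < params$mu_k, nrow = L)
    if (any(hit))
      gam[hit] <- gam[hit] +
        stats::rnorm(sum(hit), 0, params$s[[k]] * sqrt(2 * L))
    al[[k]] <- gam
  }
  gamete <- function(muts) {
    if (!length(muts)) return(integer(0))
    tab <- table(muts)
    ids <- as.integer(names(tab))
    ids[stats::runif(length(ids)) < as.integer(tab) / 2]
  }
  muts <- c(gamete(mother$muts), gamete(father$muts))
  if (params$mu_n > 0 && stats::runif(1) < params$mu_n) {
    if (is.null(new_mut_id))
      stop("'new_mut_id' required when mu_n > 0")
    muts <- c(muts, as.integer(new_mut_id))
  }
  sex <- if (stats::runif(1) < 0.5) "F" else "M"
  individual(al, muts, sex, mother$site, id,
             parents = c(mother$id, father$id))
}

#' Incompatibility distance between two individuals
#'
#' The number of incompatibility loci at which the two individuals carry
#' different alleles: the size of the symmetric difference of their carrier
#' sets (an individual carries a derived allele whether heterozygous or
#' homozygous for it).
#'
#' @param i,j `"individual"` objects, or bare integer vectors of mutation
#'   identifiers.
#' @return Non-negative integer count of divergent loci.
#' @export
incompat_distance <- function(i, j) {
  mi <- if (inherits(i, "individual")) i$muts else as.integer(i)
  mj <- if (inherits(j, "individual")) j$muts else as.integer(j)
  length(setdiff(mi, mj)) + length(setdiff(mj, mi))
}

#' Frequency-weighted incompatibility distance between subpopulations
#'
#' Records every incompatibility locus at which the two subpopulations carry
#' divergent alleles and weights each locus by its carrier frequency: the
#' distance is the sum over mutation identifiers of the absolute difference
#' in carrier frequency between the two subpopulations. When both
#' subpopulations are monomorphic this reduces to the individual-level count
#' of divergent loci.
#'
#' @param muts_A,muts_B Lists of integer vectors: the mutation-identifier set
#'   of each member of subpopulations A and B. Must be non-empty.
#' @return Non-negative real distance.
#' @export
incompat_distance_subpops <- function(muts_A, muts_B) {
  nA <- length(muts_A); nB <- length(muts_B)
  if (nA == 0L || nB == 0L) stop("subpopulations must be non-empty")
  muts_A <- lapply(muts_A, unique)  # carrier status, not dosage
  muts_B <- lapply(muts_B, unique)
  fA <- table(unlist(muts_A, use.names = FALSE)) / nA
  fB <- table(unlist(muts_B, use.names = FALSE)) / nB
  ids <- union(names(fA), names(fB))
  if (length(ids) == 0L) return(0)
  a <- numeric(length(ids)); names(a) <- ids
  b <- a
  a[names(fA)] <- fA
  b[names(fB)] <- fB
  sum(abs(a - b))
}

#' A supply of fresh mutation identifiers
#'
#' Returns a closure producing consecutive, globally unique integer
#' identifiers for new incompatibility mutations, starting from `from`.
#'
#' @param from First identifier to hand out.
#' @return A function of no arguments returning the next identifier.
#' @export
mut_id_counter <- function(from = 1L) {
  nxt <- as.integer(from) - 1L
  function() {
    nxt <<- nxt + 1L
    nxt
  }
}
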
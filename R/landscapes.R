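# Fitness landscapes on the L-locus binary hypercube.
#
# Genotypes are encoded as integers in [0, 2^L - 1]; bit i (0-based, least
# significant first) is the allele at locus i, 0 = wild type, 1 = mutant.
# The reference sequence sigma* defaults to the all-zero genotype, so the
# additive fitness component grows with the number of mutant alleles.

.max_L <- 20L

check_genotype <- function(g, L) {
  if (any(g < 0 | g > 2^L - 1 | g != floor(g))) {
    stop("genotype index out of range for L = ", L)
  }
  invisible(g)
}

#' Hamming distance between genotypes
#'
#' Number of loci at which two genotypes differ, i.e. the popcount of the
#' bitwise XOR of their integer encodings. Vectorized over `a` and `b`.
#'
#' @param a,b genotype indices in `[0, 2^L - 1]`.
#' @param L number of loci.
#' @return integer vector of distances in `[0, L]`.
#' @examples
#' hamming_distance(0L, 15L, 4)  # 4: complement
#' hamming_distance(3L, 1L, 4)   # 1: single flip
#' @export
hamming_distance <- function(a, b, L) {
  stopifnot(L >= 1, L <= .max_L)
  check_genotype(a, L)
  check_genotype(b, L)
  x <- bitwXor(as.integer(a), as.integer(b))
  d <- integer(length(x))
  for (i in seq_len(L) - 1L) {
    d <- d + bitwAnd(bitwShiftR(x, i), 1L)
  }
  d
}

#' Genotype index to bit string
#'
#' @param g genotype indices.
#' @param L number of loci.
#' @return character vector; locus 0 is the leftmost character.
#' @export
genotype_bits <- function(g, L) {
  g <- as.integer(g)
  check_genotype(g, L)
  vapply(g, function(x) {
    paste(bitwAnd(bitwShiftR(x, seq_len(L) - 1L), 1L), collapse = "")
  }, character(1))
}

#' Bit string to genotype index
#' @param bits character vector of `L`-character 0/1 strings (locus 0 first).
#' @return integer genotype indices.
#' @export
genotype_index <- function(bits) {
  vapply(bits, function(b) {
    v <- as.integer(strsplit(b, "")[[1]])
    stopifnot(all(v %in% c(0L, 1L)))
    as.integer(sum(v * 2^(seq_along(v) - 1)))
  }, integer(1), USE.NAMES = FALSE)
}

#' Landscape parameter set
#'
#' @param L number of loci (1..20).
#' @param model one of `"rmf"`, `"additive"`, `"hoc"`, `"nk"`.
#' @param c additive slope (fitness units per Hamming step from `sigma_star`).
#' @param lambda mean of the exponential random fitness component.
#' @param sigma_star reference genotype index (default 0, the all-wild-type
#'   sequence).
#' @param nk_K number of interacting neighbors per locus (NK model only),
#'   in `[0, L - 1]`.
#' @param nk_meanlog,nk_sdlog location and scale of the lognormal NK
#'   contribution distribution.
#' @param seed optional RNG seed stored with the parameters; landscapes
#'   generated from the same parameter set (including seed) are identical.
#' @return an object of class `landscape_params`.
#' @export
landscape_params <- function(L, model = c("rmf", "additive", "hoc", "nk"),
                             c = 1, lambda = 1, sigma_star = 0L,
                             nk_K = NULL, nk_meanlog = 0, nk_sdlog = 1,
                             seed = NULL) {
  model <- match.arg(model)
  if (L < 1 || L > .max_L || L != floor(L)) stop("L must be an integer in [1, ", .max_L, "]")
  L <- as.integer(L)
  if (model == "additive") lambda <- 0
  if (model == "hoc") c <- 0
  if (c < 0) stop("negative additive slope c")
  if (lambda < 0) stop("negative ruggedness parameter lambda")
  if (model == "additive" && c <= 0) stop("additive model requires c > 0")
  if (model == "hoc" && lambda <= 0) stop("house-of-cards model requires lambda > 0")
  if (model %in% c("rmf", "additive", "hoc") && c == 0 && lambda == 0) {
    stop("degenerate landscape: c = 0 and lambda = 0")
  }
  check_genotype(sigma_star, L)
  if (model == "nk") {
    if (is.null(nk_K)) stop("nk_K must be given for the NK model")
    if (nk_K < 0 || nk_K > L - 1 || nk_K != floor(nk_K)) {
      stop("nk_K must be an integer in [0, L - 1]")
    }
    nk_K <- as.integer(nk_K)
    if (nk_sdlog <= 0) stop("nk_sdlog must be positive")
  }
  structure(list(L = L, model = model, c = c, lambda = lambda,
                 sigma_star = as.integer(sigma_star), nk_K = nk_K,
                 nk_meanlog = nk_meanlog, nk_sdlog = nk_sdlog, seed = seed),
            class = "landscape_params")
}

# distances of all 2^L genotypes to a reference genotype
all_distances <- function(L, ref = 0L) {
  hamming_distance(seq_len(2^L) - 1L, as.integer(ref), L)
}

#' Generate a fitness landscape
#'
#' Draws one realization of the landscape defined by `params`.
#'
#' Rough Mount Fuji: `F(g) = c * d(g, sigma*) + eta_g`, with `eta_g` i.i.d.
#' exponential with mean `lambda` (drawn by inverse CDF from the seeded uniform
#' stream, so realizations are reproducible across platforms). `lambda = 0`
#' gives the purely additive landscape; `c = 0` gives House of Cards
#' (i.i.d. random fitness). NK: `F(g)` is the sum over loci of contributions
#' `f_i` that depend on locus `i` and its `K` circularly adjacent neighbors
#' `{i, i+1, ..., i+K} mod L`; each contribution value is i.i.d. lognormal.
#'
#' @param params a [landscape_params()] object.
#' @param seed optional seed overriding `params$seed`; `NULL` with no seed in
#'   `params` draws from the current RNG stream.
#' @return object of class `fitness_landscape`: list with `params`, `F`
#'   (length `2^L`), and `eta` (RMF random components, or NK contribution
#'   tables).
#' @examples
#' land <- generate_landscape(landscape_params(3, "additive", c = 2))
#' land$F  # 0 2 2 2 4 4 4 6
#' @export
generate_landscape <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "landscape_params"))
  with_seed(seed, {
    L <- params$L
    n <- 2^L
    if (params$model == "nk") {
      K <- params$nk_K
      tables <- lapply(seq_len(L), function(i) {
        stats::rlnorm(2^(K + 1), meanlog = params$nk_meanlog,
                      sdlog = params$nk_sdlog)
      })
      g <- seq_len(n) - 1L
      F <- numeric(n)
      for (i in seq_len(L) - 1L) {
        nb <- integer(n)
        for (j in 0:K) {
          locus <- (i + j) %% L
          nb <- nb + bitwShiftL(bitwAnd(bitwShiftR(g, locus), 1L), j)
        }
        F <- F + tables[[i + 1L]][nb + 1L]
      }
      eta <- tables
    } else {
      eta <- if (params$lambda > 0) {
        -params$lambda * log(stats::runif(n))
      } else {
        numeric(n)
      }
      F <- params$c * all_distances(L, params$sigma_star) + eta
    }
    structure(list(params = params, F = F, eta = eta),
              class = "fitness_landscape")
  })
}

#' @export
print.fitness_landscape <- function(x, ...) {
  p <- x$params
  cat(sprintf("Fitness landscape: model=%s, L=%d (%d genotypes)\n",
              p$model, p$L, length(x$F)))
  if (p$model == "nk") {
    cat(sprintf("  K=%d, lognormal(meanlog=%g, sdlog=%g)\n",
                p$nk_K, p$nk_meanlog, p$nk_sdlog))
  } else {
    cat(sprintf("  c=%g, lambda=%g, sigma*=%s\n", p$c, p$lambda,
                genotype_bits(p$sigma_star, p$L)))
  }
  cat(sprintf("  fitness range [%.4g, %.4g], %d local maxima\n",
              min(x$F), max(x$F), length(local_maxima(x))))
  invisible(x)
}

#' Local fitness maxima
#'
#' Genotypes strictly fitter than all of their `L` single-mutant neighbors.
#' Exact ties between neighboring fitness values are rejected with an error,
#' since "local maximum" is then ill-defined (ties have probability zero for
#' the continuous landscape models).
#'
#' @param land a `fitness_landscape`.
#' @return sorted integer vector of genotype indices.
#' @export
local_maxima <- function(land) {
  stopifnot(inherits(land, "fitness_landscape"))
  L <- land$params$L
  F <- land$F
  g <- seq_along(F) - 1L
  is_max <- rep(TRUE, length(F))
  for (i in seq_len(L) - 1L) {
    Fn <- F[bitwXor(g, bitwShiftL(1L, i)) + 1L]
    if (any(F == Fn)) stop("tied fitness values between neighboring genotypes")
    is_max <- is_max & (F > Fn)
  }
  g[is_max]
}

#' Density of local maxima
#'
#' Fraction of genotypes that are local maxima, averaged over `n_real`
#' independent landscape realizations, resolved by Hamming shell around
#' the reference sequence.
#'
#' @param params a [landscape_params()] object (`params$seed`, if set, seeds
#'   the whole ensemble).
#' @param n_real number of landscape realizations.
#' @return list with `per_distance` (length `L + 1`, shell densities for
#'   `d = 0..L`), `overall` (mean density over genotype space), and `n_real`.
#' @export
density_of_maxima <- function(params, n_real) {
  stopifnot(inherits(params, "landscape_params"), n_real >= 1)
  L <- params$L
  ref <- if (params$model == "nk") 0L else params$sigma_star
  d <- all_distances(L, ref)
  shell_size <- tabulate(d + 1L, nbins = L + 1L)
  acc <- numeric(L + 1L)
  overall <- 0
  with_seed(params$seed, {
    for (k in seq_len(n_real)) {
      land <- generate_landscape(params, seed = NULL)
      mx <- local_maxima(land)
      cnt <- tabulate(d[mx + 1L] + 1L, nbins = L + 1L)
      acc <- acc + cnt / shell_size
      overall <- overall + length(mx) / 2^L
    }
  })
  list(per_distance = acc / n_real, overall = overall / n_real,
       n_real = n_real)
}

#' Write a landscape to TSV (+ JSON parameter sidecar)
#'
#' Columns: `genotype_bits`, `fitness`, `eta`. Values are written with 17
#' significant digits so the round trip through [read_landscape()] is
#' lossless. The generating parameters (including the seed) go to
#' `<path>.json`. NK contribution tables are serialized in the sidecar.
#'
#' @param land a `fitness_landscape`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(land, path) {
  stopifnot(inherits(land, "fitness_landscape"))
  L <- land$params$L
  eta_col <- if (land$params$model == "nk") rep(NA_real_, 2^L) else land$eta
  df <- data.frame(
    genotype_bits = genotype_bits(seq_len(2^L) - 1L, L),
    fitness = sprintf("%.17g", land$F),
    eta = ifelse(is.na(eta_col), "NA", sprintf("%.17g", eta_col)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- land$params
  class(sidecar) <- NULL
  if (land$params$model == "nk") {
    sidecar$nk_tables <- lapply(land$eta, function(v) sprintf("%.17g", v))
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a landscape written by [write_landscape()]
#'
#' @param path TSV path (the `<path>.json` sidecar must be present).
#' @return a `fitness_landscape`.
#' @export
read_landscape <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  params <- landscape_params(
    L = meta$L, model = meta$model, c = meta$c, lambda = meta$lambda,
    sigma_star = meta$sigma_star,
    nk_K = meta$nk_K, nk_meanlog = meta$nk_meanlog %||% 0,
    nk_sdlog = meta$nk_sdlog %||% 1, seed = meta$seed
  )
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "character"))
  ord <- order(genotype_index(df$genotype_bits))
  F <- as.numeric(df$fitness)[ord]
  eta <- if (params$model == "nk") {
    lapply(meta$nk_tables, function(v) as.numeric(unlist(v)))
  } else {
    as.numeric(df$eta)[ord]
  }
  structure(list(params = params, F = F, eta = eta),
            class = "fitness_landscape")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
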
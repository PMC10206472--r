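#' Configuration for a synthetic eggshell-trait dataset
#'
#' Bundles the generating parameters for [simulate_traits()]. The defaults
#' mirror the scale of a museum/field comparative eggshell study: 45
#' species of which 14 are obligate brood parasites, 2-10 eggs per
#' species, surface roughness on the nanometre scale (baseline 2000 nm,
#' species-level SD 600 nm, egg-level SD 200 nm, hence true phylogenetic
#' heritability 0.9).
#'
#' @param n_species Number of species (tips), >= 3.
#' @param birth_rate Yule speciation rate for [simulate_tree()].
#' @param n_parasites Number of parasitic species, < `n_species`.
#' @param eggs_per_species Scalar, or length-2 range sampled uniformly per
#'   species.
#' @param mu Baseline (intercept) trait value, trait units.
#' @param sigma2_p Species-level (phylogenetic) variance, trait units^2.
#' @param sigma2_e Egg-level residual variance, trait units^2 (> 0).
#' @param beta_parasitism Fixed trait shift added to parasitic species.
#' @param convergence_w Convex pull of each parasite's species value
#'   toward its host's, in `[0, 1]`; 0 = none, 1 = parasite equals host.
#' @param host_assignment `"random"` (uniform non-parasite) or
#'   `"nearest_nonparasite"` (smallest patristic distance).
#' @param trait_name Name of the generated trait column.
#' @return A list of class `simulation_config`; `true_h2` is derived.
#' @export
simulation_config <- function(n_species = 45, birth_rate = 1,
                              n_parasites = 14,
                              eggs_per_species = c(2, 10),
                              mu = 2000, sigma2_p = 3.6e5, sigma2_e = 4e4,
                              beta_parasitism = 0, convergence_w = 0,
                              host_assignment = c("random",
                                                  "nearest_nonparasite"),
                              trait_name = "Sa") {
  host_assignment <- match.arg(host_assignment)
  stopifnot(n_species >= 3, n_parasites >= 1, n_parasites < n_species,
            sigma2_p >= 0, sigma2_e > 0,
            convergence_w >= 0, convergence_w <= 1,
            length(eggs_per_species) %in% 1:2, all(eggs_per_species >= 1))
  structure(list(
    n_species = as.integer(n_species), birth_rate = birth_rate,
    n_parasites = as.integer(n_parasites),
    eggs_per_species = as.integer(eggs_per_species), mu = mu,
    sigma2_p = sigma2_p, sigma2_e = sigma2_e,
    beta_parasitism = beta_parasitism, convergence_w = convergence_w,
    host_assignment = host_assignment, trait_name = trait_name,
    true_h2 = sigma2_p / (sigma2_p + sigma2_e)
  ), class = "simulation_config")
}

#' Simulate a Yule (pure-birth) tree
#'
#' Forward-in-time pure-birth simulation: starting from two lineages,
#' each of `k` live lineages splits after an exponential waiting time with
#' total rate `k * birth_rate`; growth stops when `n_species` lineages
#' exist and tips are extended by one further exponential waiting time so
#' the final split is interior. The tree is ultrametric; by default it is
#' rescaled to unit root-to-tip height.
#'
#' @param n_species Number of tips, >= 3.
#' @param birth_rate Speciation rate (events per lineage per time unit).
#' @param seed Integer seed; a fixed seed reproduces the tree exactly.
#' @param rescale Rescale to unit height (default `TRUE`). With
#'   `rescale = FALSE` branch lengths are in 1/birth_rate time units.
#' @return An ultrametric `phylo` with tips `s01`, `s02`, ...
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = 1,
                          rescale = TRUE) {
  stopifnot(n_species >= 3, birth_rate > 0)
  n <- as.integer(n_species)
  sim <- withr::with_seed(seed, {
    parent <- c(NA_integer_, 1L, 1L)   # node 1 = root, 2:3 its children
    btime <- c(0, 0, 0)
    alive <- c(2L, 3L)
    t_now <- 0
    while (length(alive) < n) {
      k <- length(alive)
      t_now <- t_now + stats::rexp(1, rate = k * birth_rate)
      i <- alive[sample.int(k, 1L)]
      id <- length(parent) + 1:2
      parent <- c(parent, i, i)
      btime <- c(btime, t_now, t_now)
      alive <- c(setdiff(alive, i), id)
    }
    t_end <- t_now + stats::rexp(1, rate = n * birth_rate)
    list(parent = parent, btime = btime, alive = alive, t_end = t_end)
  })
  children <- split(seq_along(sim$parent)[-1], sim$parent[-1])
  labels <- character(length(sim$parent))
  labels[sim$alive] <- sprintf("s%0*d", max(2L, nchar(n)), seq_len(n))
  dt <- ifelse(seq_along(sim$parent) %in% sim$alive, sim$t_end, NA)
  for (v in as.integer(names(children)))
    dt[v] <- sim$btime[children[[as.character(v)]][1]]
  newick <- function(v) {
    kids <- children[[as.character(v)]]
    core <- if (is.null(kids)) labels[v]
    else paste0("(", paste(vapply(kids, newick, character(1)),
                           collapse = ","), ")")
    if (v == 1L) paste0(core, ";")
    else paste0(core, ":", format(dt[v] - sim$btime[v], digits = 15))
  }
  tree <- ape::read.tree(text = newick(1L))
  if (rescale) tree$edge.length <- tree$edge.length / sim$t_end
  validate_phylogeny(tree)
  tree
}

#' Simulate an egg-level trait dataset on a tree
#'
#' Species effects are drawn from a multivariate normal with covariance
#' `sigma2_p * A` (A the standardized Brownian covariance of the tree, via
#' Cholesky); parasitic species then receive the fixed shift
#' `beta_parasitism` and are pulled toward their assigned host's species
#' value by the convex weight `convergence_w`
#' (`s_p <- (1 - w) s_p + w s_host`). Egg values add i.i.d. Gaussian noise
#' of variance `sigma2_e`. Every generating parameter is recorded in the
#' returned `truth` so recovery can be scored.
#'
#' @param tree Ultrametric `phylo` with at least `config$n_species` tips;
#'   typically from [simulate_tree()].
#' @param config A [simulation_config()].
#' @param seed Integer seed; the dataset is a pure function of
#'   `(tree, config, seed)`.
#' @return Object of class `synthetic_dataset`: list with `tree`, `eggs`
#'   (egg table), `hostmap`, `truth` (config values plus the realized
#'   parasite set, host assignment and species effects).
#' @export
simulate_traits <- function(tree, config, seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  validate_phylogeny(tree)
  sp <- tree$tip.label
  if (length(sp) != config$n_species)
    stop("tree has ", length(sp), " tips but config expects ",
         config$n_species, call. = FALSE)
  pc <- phylo_covariance(tree)
  A <- pc$A[sp, sp]
  withr::with_seed(seed, {
    u <- if (config$sigma2_p > 0) {
      L <- tryCatch(chol(config$sigma2_p * A), error = function(e)
        stop("species covariance is not positive definite: ",
             conditionMessage(e), call. = FALSE))
      drop(t(L) %*% stats::rnorm(length(sp)))
    } else rep(0, length(sp))
    names(u) <- sp

    parasites <- sort(sample(sp, config$n_parasites))
    nonpara <- setdiff(sp, parasites)
    host_of <- if (config$host_assignment == "random") {
      stats::setNames(sample(nonpara, config$n_parasites,
                             replace = TRUE), parasites)
    } else {
      D <- ape::cophenetic.phylo(tree)
      stats::setNames(vapply(parasites, function(p)
        nonpara[which.min(D[p, nonpara])], character(1)), parasites)
    }

    s_val <- config$mu + u
    s_val[parasites] <- s_val[parasites] + config$beta_parasitism
    w <- config$convergence_w
    s_val[parasites] <- (1 - w) * s_val[parasites] +
      w * s_val[host_of[parasites]]

    m <- if (length(config$eggs_per_species) == 2L) {
      sample(config$eggs_per_species[1]:config$eggs_per_species[2],
             length(sp), replace = TRUE)
    } else rep(config$eggs_per_species, length(sp))
    names(m) <- sp

    species_col <- rep(sp, times = m)
    vals <- rep(s_val, times = m) +
      stats::rnorm(sum(m), sd = sqrt(config$sigma2_e))
    eggs <- data.frame(
      egg_id = sprintf("egg%04d", seq_along(vals)),
      species = species_col,
      parasitic = species_col %in% parasites,
      hosts = ifelse(species_col %in% parasites,
                     host_of[species_col], NA_character_),
      stringsAsFactors = FALSE)
    eggs[[config$trait_name]] <- vals

    structure(list(
      tree = tree, eggs = eggs,
      hostmap = data.frame(parasite = parasites,
                           host = unname(host_of[parasites]),
                           stringsAsFactors = FALSE),
      truth = c(unclass(config),
                list(seed = seed, parasites = parasites,
                     host_of = as.list(host_of),
                     species_values = as.list(s_val),
                     eggs_per_species_realized = as.list(m)))
    ), class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic eggshell dataset:", length(x$tree$tip.label), "species (",
      length(x$truth$parasites), "parasitic ),", nrow(x$eggs), "eggs\n")
  cat(sprintf("  trait %s: true H2 = %.3f, beta_parasitism = %g, w = %g\n",
              x$truth$trait_name, x$truth$true_h2,
              x$truth$beta_parasitism, x$truth$convergence_w))
  invisible(x)
}

#' Simulate a profilometry height map
#'
#' A smooth quadratic surface (the fragment's curvature) plus an i.i.d.
#' Gaussian roughness field. With `roughness_sd = s`, the expected Sa
#' after exact quadratic detrending is `s * sqrt(2/pi)` (the mean absolute
#' value of a centered normal).
#'
#' @param rows,cols Grid dimensions (pixels), each >= 8.
#' @param curvature_coeffs Length-6 numeric `c(a, b, c, d, e, f)` for
#'   `z = a x^2 + b x y + c y^2 + d x + e y + f` over centered pixel
#'   indices.
#' @param roughness_sd SD of the Gaussian roughness field (nm), >= 0.
#' @param seed Integer seed; a fixed seed reproduces the grid exactly.
#' @return Numeric `rows x cols` matrix of heights (nm).
#' @export
simulate_heightmap <- function(rows, cols,
                               curvature_coeffs = c(0.01, 0, 0.01, 0, 0, 0),
                               roughness_sd = 1000, seed = 1) {
  stopifnot(rows >= 8, cols >= 8, roughness_sd >= 0,
            length(curvature_coeffs) == 6)
  x <- seq_len(cols) - (cols + 1) / 2
  y <- seq_len(rows) - (rows + 1) / 2
  cc <- curvature_coeffs
  base <- outer(y, x, function(yy, xx)
    cc[1] * xx^2 + cc[2] * xx * yy + cc[3] * yy^2 +
      cc[4] * xx + cc[5] * yy + cc[6])
  noise <- withr::with_seed(seed,
    matrix(stats::rnorm(rows * cols, sd = roughness_sd), nrow = rows))
  base + noise
}

#' Write a synthetic dataset to disk
#'
#' Emits the same formats the analysis pipeline consumes — `tree.nwk`
#' (Newick), `eggs.csv`, `hostmap.csv` — plus `truth.json` with the full
#' generating configuration.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_newick(dataset$tree, file.path(dir, "tree.nwk"))
  write_eggs(dataset$eggs, file.path(dir, "eggs.csv"))
  utils::write.csv(dataset$hostmap, file.path(dir, "hostmap.csv"),
                   row.names = FALSE, quote = TRUE)
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
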
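#' Read a parasite-to-host map
#'
#' Two-column CSV (`parasite`, `host`); a parasite with several candidate
#' hosts occupies several rows.
#'
#' @param file Path to the CSV.
#' @return A `data.frame` with columns `parasite` and `host`.
#' @export
read_hostmap <- function(file) {
  if (!file.exists(file)) stop("host map not found: ", file, call. = FALSE)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_hostmap(df)
}

#' Validate a parasite-to-host map
#' @param map `data.frame` with character columns `parasite`, `host`.
#' @param eggs Optional egg table; if given, every host must appear as a
#'   non-parasitic species in it.
#' @return The map, deduplicated.
#' @export
validate_hostmap <- function(map, eggs = NULL) {
  need <- c("parasite", "host")
  if (!all(need %in% names(map)))
    stop("host map needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  map <- unique(map[, need])
  map$parasite <- as.character(map$parasite)
  map$host <- as.character(map$host)
  self <- map$parasite == map$host
  if (any(self))
    stop("parasite mapped to itself: ",
         paste(unique(map$parasite[self]), collapse = ", "), call. = FALSE)
  if (!is.null(eggs)) {
    para_sp <- unique(eggs$species[eggs$parasitic])
    bad <- map$host %in% para_sp
    if (any(bad))
      stop("host species are parasitic in the egg table: ",
           paste(unique(map$host[bad]), collapse = ", "), call. = FALSE)
  }
  rownames(map) <- NULL
  map
}

hosts_of <- function(map, parasite) unique(map$host[map$parasite == parasite])

#' Host reference trait value for one parasitic egg
#'
#' Supplies the "host side" of a parasite-host pair. With a single
#' candidate host species the partner is either one of that host's eggs
#' sampled uniformly (`rule = "egg_sample"`, mirroring egg-by-egg pairing)
#' or the host species' mean (`rule = "species_mean"`). When several
#' candidate host species exist and the laying host of the particular egg
#' is unknown (the common-cuckoo situation), the reference is always the
#' mean of the candidate host species' mean trait values.
#'
#' @param parasite_species Species label of the parasitic egg.
#' @param eggs Egg table (see [validate_eggs()]).
#' @param map Host map (see [read_hostmap()]).
#' @param trait Trait column name (`"Sa"`, `"CA"` or `"CaCO3"`).
#' @param rule `"egg_sample"` or `"species_mean"` for single-host
#'   parasites; multi-host parasites always use the mean-of-host-means.
#' @return The reference value, or `NA` (with a warning) when no host of
#'   this parasite has trait data.
#' @export
host_reference_value <- function(parasite_species, eggs, map, trait,
                                 rule = c("egg_sample", "species_mean")) {
  rule <- match.arg(rule)
  hosts <- hosts_of(map, parasite_species)
  if (!length(hosts)) {
    warning("no hosts mapped for parasite '", parasite_species, "'",
            call. = FALSE)
    return(NA_real_)
  }
  vals_by_host <- lapply(hosts, function(h) {
    v <- eggs[[trait]][eggs$species == h]
    v[is.finite(v)]
  })
  have <- lengths(vals_by_host) > 0L
  if (!any(have)) {
    warning("no measured ", trait, " for any host of '", parasite_species,
            "'; pair skipped", call. = FALSE)
    return(NA_real_)
  }
  vals_by_host <- vals_by_host[have]
  if (length(vals_by_host) > 1L)
    return(mean(vapply(vals_by_host, mean, numeric(1))))
  v <- vals_by_host[[1]]
  switch(rule,
         egg_sample = v[sample.int(length(v), 1L)],
         species_mean = mean(v))
}

#' Build parasite-host and parasite-random egg pairs
#'
#' For each parasitic egg with a measured trait value, constructs (a) a
#' host pair against that parasite's host reference value (see
#' [host_reference_value()]) and (b) a random pair against an egg sampled
#' uniformly from the non-parasitic eggs, by default excluding the focal
#' parasite's own host species so the random group is a genuine
#' non-host contrast. Pair differences are absolute differences of
#' per-egg trait means.
#'
#' @param eggs Egg table.
#' @param map Host map.
#' @param trait Trait column name.
#' @param seed Integer seed; the pairing is a pure function of
#'   `(eggs, map, trait, seed, ...)`.
#' @param host_rule Passed to [host_reference_value()].
#' @param exclude_hosts Should random partners exclude the focal
#'   parasite's host species? Default `TRUE`; set `FALSE` for sensitivity
#'   analysis.
#' @param target_counts Optional `c(host = , random = )` totals; pairs of
#'   each type are subsampled (seeded) down to these counts, mimicking
#'   datasets where not every parasitic egg yields both pair types.
#' @return Object of class `pairing_set`: a `data.frame` with columns
#'   `egg_id`, `parasite_species`, `pair_type` (`"host"`/`"random"`),
#'   `partner` (partner description), `abs_difference`; attributes `seed`,
#'   `trait`, `n_host`, `n_random`.
#' @export
build_pairs <- function(eggs, map, trait, seed, host_rule = "egg_sample",
                        exclude_hosts = TRUE, target_counts = NULL) {
  stopifnot(trait %in% names(eggs))
  map <- validate_hostmap(map, eggs)
  para <- eggs[eggs$parasitic & is.finite(eggs[[trait]]), , drop = FALSE]
  if (!nrow(para)) {
    warning("no parasitic eggs with measured ", trait,
            "; empty pairing set", call. = FALSE)
    empty <- data.frame(egg_id = character(), parasite_species = character(),
                        pair_type = character(), partner = character(),
                        abs_difference = numeric())
    return(structure(empty, class = c("pairing_set", "data.frame"),
                     seed = seed, trait = trait, n_host = 0L, n_random = 0L))
  }
  nonpara <- eggs[!eggs$parasitic & is.finite(eggs[[trait]]), , drop = FALSE]
  rows <- withr::with_seed(seed, {
    out <- vector("list", 2L * nrow(para))
    k <- 0L
    for (i in seq_len(nrow(para))) {
      pv <- para[[trait]][i]
      psp <- para$species[i]
      hosts <- hosts_of(map, psp)
      ref <- suppressWarnings(
        host_reference_value(psp, eggs, map, trait, rule = host_rule))
      if (is.finite(ref)) {
        k <- k + 1L
        out[[k]] <- data.frame(
          egg_id = para$egg_id[i], parasite_species = psp,
          pair_type = "host", partner = paste(hosts, collapse = ";"),
          abs_difference = abs(pv - ref))
      } else {
        warning("host pair skipped for egg '", para$egg_id[i],
                "' (no host data)", call. = FALSE)
      }
      cand <- nonpara
      if (exclude_hosts && length(hosts))
        cand <- cand[!cand$species %in% hosts, , drop = FALSE]
      if (nrow(cand)) {
        j <- sample.int(nrow(cand), 1L)
        k <- k + 1L
        out[[k]] <- data.frame(
          egg_id = para$egg_id[i], parasite_species = psp,
          pair_type = "random", partner = cand$egg_id[j],
          abs_difference = abs(pv - cand[[trait]][j]))
      } else {
        warning("random pair skipped for egg '", para$egg_id[i],
                "' (no eligible non-host partner)", call. = FALSE)
      }
    }
    pairs <- do.call(rbind, out[seq_len(k)])
    if (!is.null(target_counts)) {
      pairs <- do.call(rbind, lapply(c("host", "random"), function(ty) {
        sub <- pairs[pairs$pair_type == ty, , drop = FALSE]
        want <- target_counts[[ty]]
        if (is.null(want) || want >= nrow(sub)) return(sub)
        sub[sort(sample.int(nrow(sub), want)), , drop = FALSE]
      }))
    }
    pairs
  })
  rownames(rows) <- NULL
  structure(rows, class = c("pairing_set", "data.frame"),
            seed = seed, trait = trait,
            n_host = sum(rows$pair_type == "host"),
            n_random = sum(rows$pair_type == "random"))
}

#' @export
print.pairing_set <- function(x, ...) {
  cat("Pairing set (", attr(x, "trait"), "): ", attr(x, "n_host"),
      " host pairs, ", attr(x, "n_random"),
      " random pairs (seed ", attr(x, "seed"), ")\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Compare host-pair and random-pair absolute differences
#'
#' Tests whether parasite eggs are closer in trait value to their hosts'
#' eggs than to random non-parasitic eggs. The estimate is the difference
#' in mean absolute pair difference, random minus host (positive when
#' parasites resemble their hosts more than chance); its SE, t and
#' parametric p come from the two-group ordinary least squares fit
#' (df = n_pairs - 2). A permutation p-value is computed alongside by
#' shuffling the pair-type labels across pairs `n_permutations` times
#' (seeded) and counting permuted |estimate| >= observed |estimate|,
#' with the +1/(B+1) finite-sample correction.
#'
#' @param pairs A `pairing_set` (or `data.frame` with `pair_type` and
#'   `abs_difference`), at least 2 pairs of each type.
#' @param n_permutations Number of label shuffles, default 10000.
#' @param seed Integer seed for the shuffles.
#' @return Object of class `group_comparison`: list with `estimate`, `se`,
#'   `t`, `df`, `p_parametric`, `p_permutation`, `n_host_pairs`,
#'   `n_random_pairs`, `n_permutations`, `seed`.
#' @export
compare_pair_types <- function(pairs, n_permutations = 10000, seed = 1) {
  d <- pairs$abs_difference
  is_host <- pairs$pair_type == "host"
  n_h <- sum(is_host); n_r <- sum(!is_host)
  if (n_h < 2L || n_r < 2L)
    stop("need at least 2 pairs of each type (host: ", n_h,
         ", random: ", n_r, ")", call. = FALSE)
  n <- n_h + n_r
  est <- mean(d[!is_host]) - mean(d[is_host])
  ss <- sum((d[is_host] - mean(d[is_host]))^2) +
    sum((d[!is_host] - mean(d[!is_host]))^2)
  df <- n - 2L
  se <- sqrt(ss / df * (1 / n_h + 1 / n_r))
  tstat <- if (se > 0) est / se else 0
  p_par <- 2 * stats::pt(-abs(tstat), df = df)
  # permuted estimate from the host-group sum alone: avoids refitting
  tot <- sum(d)
  est_from_hsum <- function(hs) (tot - hs) / n_r - hs / n_h
  tol <- 1e-12 * max(abs(d), 1)
  exceed <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(b) {
      hs <- sum(d[sample.int(n, n_h)])
      abs(est_from_hsum(hs)) >= abs(est) - tol
    }, logical(1)))
  })
  structure(list(
    estimate = est, se = se, t = tstat, df = df,
    p_parametric = p_par,
    p_permutation = (1 + exceed) / (n_permutations + 1),
    n_host_pairs = n_h, n_random_pairs = n_r,
    n_permutations = n_permutations, seed = seed
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Host-match comparison: estimate = %.4g, s.e. = %.4g, t(%d) = %.3f\n",
    x$estimate, x$se, x$df, x$t))
  cat(sprintf("  parametric p = %.4g; permutation p = %.4g (B = %d)\n",
              x$p_parametric, x$p_permutation, x$n_permutations))
  cat(sprintf("  %d host pairs vs %d random pairs\n",
              x$n_host_pairs, x$n_random_pairs))
  invisible(x)
}
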
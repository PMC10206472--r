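#' Descriptive summary of an egg table
#'
#' Per-trait, per-group (parasitic vs non-parasitic) minimum, maximum,
#' mean and SD of the per-egg values, plus wettability category tallies
#' from the measured contact angles. Groups with no data yield an empty
#' (all-`NA`) row rather than an error.
#'
#' @param eggs Egg table (see [validate_eggs()]).
#' @param traits Trait columns to summarize.
#' @return List with `traits` (a `data.frame`) and `wettability` (named
#'   counts).
#' @export
descriptive_summary <- function(eggs, traits = c("Sa", "CA", "CaCO3")) {
  stopifnot(nrow(eggs) > 0)
  traits <- intersect(traits, names(eggs))
  rows <- do.call(rbind, lapply(traits, function(tr) {
    do.call(rbind, lapply(c(TRUE, FALSE), function(par) {
      v <- eggs[[tr]][eggs$parasitic == par]
      v <- v[is.finite(v)]
      data.frame(trait = tr,
                 group = if (par) "parasitic" else "non-parasitic",
                 n = length(v),
                 min = if (length(v)) min(v) else NA_real_,
                 max = if (length(v)) max(v) else NA_real_,
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) stats::sd(v) else NA_real_)
    }))
  }))
  rownames(rows) <- NULL
  wett <- if ("CA" %in% names(eggs)) {
    ca <- eggs$CA[is.finite(eggs$CA)]
    cls <- factor(classify_wettability(ca),
                  levels = c("hydrophilic", "hydrophobic",
                             "superhydrophobic"))
    as.list(table(cls))
  } else list()
  list(traits = rows, wettability = wett)
}

derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647) + 1L
}

#' Run the full comparative analysis
#'
#' Orchestrates, in order: egg-table validation and tree reconciliation;
#' a phylogenetic mixed model per requested trait with parasitic status
#' as predictor, its heritability and the likelihood-ratio test of the
#' status effect; an ordinary (identity-covariance) mixed model of CA on
#' Sa with a species random effect; Pearson correlations of Sa and CA
#' (all eggs, parasitic only, non-parasitic only); the descriptive
#' summary; and, when a host map is supplied, the host-match pairing and
#' permutation comparison per trait. All randomness descends from `seed`,
#' split deterministically per stage, so the report is reproducible.
#'
#' @param tree A `phylo` with branch lengths (see [grafen_branch_lengths()]
#'   for topologies without them, requested via `grafen = TRUE`).
#' @param eggs Egg table (`data.frame` or CSV path).
#' @param hostmap Optional host map (`data.frame` or CSV path).
#' @param traits Traits to analyze, subset of `c("Sa", "CA", "CaCO3")`.
#' @param n_permutations Label shuffles for each host-match test.
#' @param seed Top-level integer seed.
#' @param strict Abort (rather than drop with a warning) on invalid trait
#'   values or on table species missing from the tree.
#' @param grafen Assign Grafen branch lengths when the tree has none.
#' @param exclude_hosts Host-exclusion rule for random partners, see
#'   [build_pairs()].
#' @param host_rule Host reference rule, see [host_reference_value()].
#' @return Object of class `analysis_report` (nested list; see
#'   [write_report()]).
#' @export
run_analysis <- function(tree, eggs, hostmap = NULL,
                         traits = c("Sa", "CA", "CaCO3"),
                         n_permutations = 10000, seed = 1, strict = FALSE,
                         grafen = FALSE, exclude_hosts = TRUE,
                         host_rule = "egg_sample") {
  traits <- match.arg(traits, several.ok = TRUE)
  if (is.character(eggs)) eggs <- read_eggs(eggs, strict = strict)
  else eggs <- validate_eggs(eggs, strict = strict)
  if (is.character(hostmap)) hostmap <- read_hostmap(hostmap)
  if (is.character(tree)) tree <- read_phylogeny(tree)
  if (is.null(tree$edge.length)) {
    if (!grafen)
      stop("tree has no branch lengths; pass grafen = TRUE to assign ",
           "Grafen lengths explicitly", call. = FALSE)
    tree <- grafen_branch_lengths(tree)
  }

  absent <- setdiff(unique(eggs$species), tree$tip.label)
  if (length(absent)) {
    msg <- paste0(length(absent), " species in the egg table are absent ",
                  "from the tree: ", paste(absent, collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, " -- their eggs are dropped", call. = FALSE)
    eggs <- eggs[!eggs$species %in% absent, , drop = FALSE]
  }
  if (length(unique(eggs$species)) < 3L)
    stop("fewer than 3 species shared between table and tree", call. = FALSE)
  pc <- phylo_covariance(tree, taxa = unique(eggs$species))

  pmm_block <- function(tr) {
    dat <- eggs[is.finite(eggs[[tr]]), , drop = FALSE]
    if (length(unique(dat$species)) < 3L || nrow(dat) < 5L)
      return(list(note = paste0("insufficient data for ", tr)))
    f_full <- stats::as.formula(paste(tr, "~ parasitic"))
    f_red <- stats::as.formula(paste(tr, "~ 1"))
    fit <- fit_pmm(f_full, dat, A = pc$A, criterion = "REML")
    lrt <- lrt_fixed_effect(f_full, f_red, dat, A = pc$A)
    list(
      n_eggs = fit$n, n_species = fit$n_species,
      fixed_effects = fit$beta,
      sigma2_p = fit$sigma2_p, sigma2_e = fit$sigma2_e,
      H2 = heritability(fit), boundary = fit$boundary,
      loglik_reml = fit$loglik_reml,
      lrt = list(chi2 = lrt$chi2, df = lrt$df, p = lrt$p)
    )
  }
  pmm <- stats::setNames(lapply(traits, pmm_block), traits)

  ca_sa <- NULL
  if (all(c("Sa", "CA") %in% traits)) {
    both <- eggs[is.finite(eggs$Sa) & is.finite(eggs$CA), , drop = FALSE]
    ca_sa <- tryCatch({
      fit <- fit_pmm(CA ~ Sa, both, A = NULL, criterion = "REML")
      lrt <- lrt_fixed_effect(CA ~ Sa, CA ~ 1, both, A = NULL)
      list(n_eggs = fit$n, n_species = fit$n_species,
           fixed_effects = fit$beta, sigma2_species = fit$sigma2_p,
           sigma2_resid = fit$sigma2_e,
           lrt = list(chi2 = lrt$chi2, df = lrt$df, p = lrt$p))
    }, error = function(e) list(note = conditionMessage(e)))
    cor_block <- function(sub) {
      tryCatch({
        r <- pearson_ci(sub$Sa, sub$CA)
        list(r = r$r, ci_low = r$ci_low, ci_high = r$ci_high, n = r$n)
      }, error = function(e) list(note = conditionMessage(e)))
    }
    correlations <- list(
      all = cor_block(both),
      parasitic = cor_block(both[both$parasitic, , drop = FALSE]),
      non_parasitic = cor_block(both[!both$parasitic, , drop = FALSE]))
  } else correlations <- NULL

  hostmatch <- NULL
  if (!is.null(hostmap)) {
    hostmatch <- stats::setNames(lapply(traits, function(tr) {
      prs <- withCallingHandlers(
        build_pairs(eggs, hostmap, tr,
                    seed = derive_seed(seed, paste0("pairs_", tr)),
                    host_rule = host_rule, exclude_hosts = exclude_hosts),
        warning = function(w) invokeRestart("muffleWarning"))
      if (attr(prs, "n_host") < 2L || attr(prs, "n_random") < 2L)
        return(list(note = paste0("too few pairs for ", tr)))
      cmp <- compare_pair_types(prs, n_permutations = n_permutations,
                                seed = derive_seed(seed,
                                                   paste0("perm_", tr)))
      unclass(cmp)
    }), traits)
  }

  structure(list(
    package_version = as.character(utils::packageVersion("shelltraits")),
    config = list(traits = traits, n_permutations = n_permutations,
                  seed = seed, strict = strict, grafen = grafen,
                  exclude_hosts = exclude_hosts, host_rule = host_rule,
                  n_species_dropped = length(absent)),
    descriptives = descriptive_summary(eggs, traits),
    pmm = pmm, ca_on_sa = ca_sa, correlations = correlations,
    hostmatch = hostmatch
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Eggshell comparative analysis (seed ", x$config$seed, ") ==\n",
      sep = "")
  for (tr in names(x$pmm)) {
    b <- x$pmm[[tr]]
    if (!is.null(b$note)) { cat(tr, ":", b$note, "\n"); next }
    est <- b$fixed_effects[b$fixed_effects$term != "(Intercept)", ]
    cat(sprintf(
      "%s: PMM estimate = %.4g, s.e. = %.4g, t = %.2f, p = %.3g (chi2 LRT)\n",
      tr, est$estimate[1], est$se[1], est$t[1], b$lrt$p))
    cat(sprintf("    H2 = %.2f  (sigma2_p = %.4g, sigma2_e = %.4g)%s\n",
                b$H2, b$sigma2_p, b$sigma2_e,
                if (b$boundary) "  [boundary]" else ""))
  }
  if (!is.null(x$correlations) && is.null(x$correlations$all$note)) {
    ca <- x$correlations$all
    cat(sprintf("Sa~CA Pearson r = %.3f, 95%% CI [%.3f, %.3f], n = %d\n",
                ca$r, ca$ci_low, ca$ci_high, ca$n))
  }
  if (!is.null(x$hostmatch)) {
    for (tr in names(x$hostmatch)) {
      h <- x$hostmatch[[tr]]
      if (!is.null(h$note)) { cat("host-match ", tr, ": ", h$note, "\n",
                                  sep = ""); next }
      cat(sprintf(
        "host-match %s: estimate = %.4g, s.e. = %.4g, t(%d) = %.2f, perm p = %.4g\n",
        tr, h$estimate, h$se, h$df, h$t, h$p_permutation))
    }
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Serializes the report as machine-readable JSON plus a human-readable
#' markdown rendering of the same numbers; reruns with identical inputs
#' and seed produce byte-identical files.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return Named vector of the paths written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  md <- file.path(dir, "report.md")
  txt <- utils::capture.output(print(report))
  writeLines(c("```", txt, "```"), md)
  invisible(c(json = json, markdown = md))
}
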
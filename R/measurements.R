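#' Surface roughness Sa from a profilometry height map
#'
#' Fits a second-order polynomial reference surface
#' `z ~ a x^2 + b x y + c y^2 + d x + e y + f` to the full pixel grid by
#' ordinary least squares (the plane correction for curved eggshell
#' fragments) and returns the arithmetic mean absolute deviation of the
#' heights from that surface — the areal roughness parameter Sa, in the
#' units of the input grid (nanometres for profilometer output).
#'
#' @param grid Numeric matrix of surface heights (rows x cols of pixels),
#'   all values finite, at least 6 pixels.
#' @return Sa, a non-negative scalar in input units.
#' @export
#' @examples
#' g <- outer(1:50, 1:40, function(r, c) 2 * r^2 + r * c - c)  # pure quadratic
#' compute_sa(g)  # ~0: quadratic detrending removes it all
compute_sa <- function(grid) {
  grid <- as.matrix(grid)
  if (!is.numeric(grid)) stop("height map must be numeric", call. = FALSE)
  if (any(!is.finite(grid)))
    stop("height map contains non-finite values", call. = FALSE)
  if (length(grid) < 6L)
    stop("height map must contain at least 6 pixels for a quadratic fit",
         call. = FALSE)
  nr <- nrow(grid); nc <- ncol(grid)
  # centered pixel indices keep the normal equations well conditioned
  x <- rep(seq_len(nc) - (nc + 1) / 2, each = nr)
  y <- rep(seq_len(nr) - (nr + 1) / 2, times = nc)
  X <- cbind(1, x, y, x * x, x * y, y * y)
  qrX <- qr(X)
  if (qrX$rank < 6L)
    stop("degenerate plane correction: quadratic design is rank-deficient (",
         "rank ", qrX$rank, " < 6); pixels may be collinear", call. = FALSE)
  res <- qr.resid(qrX, as.vector(grid))
  mean(abs(res))
}

#' Per-egg mean surface roughness
#'
#' Eggs are scanned at several (typically four) non-overlapping locations;
#' the egg-level Sa is the arithmetic mean of the per-scan values.
#'
#' @param scans Numeric vector of 1 to 10 positive per-scan Sa values (nm).
#' @return Mean Sa (nm).
#' @export
egg_mean_sa <- function(scans) {
  if (length(scans) < 1L)
    stop("no scans supplied for egg-level mean", call. = FALSE)
  if (length(scans) > 10L)
    stop("more than 10 scans per egg is not supported", call. = FALSE)
  if (any(!is.finite(scans)) || any(scans <= 0))
    stop("per-scan Sa values must be finite and positive", call. = FALSE)
  mean(scans)
}

#' Classify surface wettability from contact angle
#'
#' Thresholds: hydrophilic for CA < 90 degrees, hydrophobic for
#' 90 <= CA < 150, superhydrophobic for CA >= 150. Boundary values
#' classify upward.
#'
#' @param ca Numeric vector of contact angles in degrees, each in (0, 180).
#' @return Character vector of `"hydrophilic"`, `"hydrophobic"`,
#'   `"superhydrophobic"`.
#' @export
classify_wettability <- function(ca) {
  if (any(!is.finite(ca)) || any(ca <= 0) || any(ca >= 180))
    stop("contact angles must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  ifelse(ca >= 150, "superhydrophobic",
         ifelse(ca >= 90, "hydrophobic", "hydrophilic"))
}

#' Contact angle at droplet settling (5 s)
#'
#' The drop-shape analyzer records the left- and right-hand contact angle
#' once per second; droplet spreading is negligible after 5 seconds, so
#' the egg's CA is the mean of the left and right readings at the 5 s mark.
#'
#' @param left,right Numeric vectors of per-second readings (degrees),
#'   each of length at least 5 (index 5 is the 5 s mark).
#' @return CA in degrees.
#' @export
ca_at_settle <- function(left, right) {
  if (length(left) < 5L || length(right) < 5L)
    stop("need at least 5 per-second readings on each side", call. = FALSE)
  if (!is.finite(left[5]) || !is.finite(right[5]))
    stop("readings at the 5 s mark must be finite", call. = FALSE)
  (left[5] + right[5]) / 2
}

#' Calcium-carbonate content from ashing masses
#'
#' The dried shell fragment is combusted in a muffle furnace; the ash that
#' remains is taken as the CaCO3 (mineral) fraction. All masses are in
#' grams, weighed with the crucible; the empty-crucible mass is deducted.
#'
#' @param crucible Mass of the empty crucible (g).
#' @param crucible_dry Mass of crucible plus dried shell fragment (g).
#' @param crucible_ash Mass of crucible plus ash after combustion (g).
#' @return CaCO3 content as a percentage of the fragment's dry mass,
#'   in `[0, 100]`.
#' @export
#' @examples
#' caco3_percent(10.0000, 11.0000, 10.9500)  # 95
caco3_percent <- function(crucible, crucible_dry, crucible_ash) {
  if (any(!is.finite(c(crucible, crucible_dry, crucible_ash))))
    stop("masses must be finite", call. = FALSE)
  dry <- crucible_dry - crucible
  ash <- crucible_ash - crucible
  if (ash < 0)
    stop("invariant violated: ash mass below empty-crucible mass",
         call. = FALSE)
  if (dry <= 0)
    stop("dry shell mass must be positive", call. = FALSE)
  if (ash > dry)
    stop("invariant violated: ash mass (", format(ash),
         " g) exceeds dry mass (", format(dry), " g)", call. = FALSE)
  100 * ash / dry
}

#' Read a height map from delimited text
#'
#' One text row per pixel row, numeric columns; separator auto-detected
#' between comma and whitespace unless given.
#'
#' @param file Path to the grid file.
#' @param sep Field separator; default `""` (any whitespace) or `","` if
#'   the first line contains a comma.
#' @return Numeric matrix of heights.
#' @export
read_heightmap <- function(file, sep = NULL) {
  if (!file.exists(file)) stop("height map file not found: ", file,
                               call. = FALSE)
  if (is.null(sep)) {
    first <- readLines(file, n = 1L)
    sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  }
  m <- as.matrix(utils::read.table(file, sep = sep, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

# -- egg tables ---------------------------------------------------------------

egg_columns <- c("egg_id", "species", "parasitic", "hosts",
                 "Sa", "CA", "CaCO3", "nest_type", "source")

#' Read an egg-level trait table
#'
#' CSV with header columns `egg_id, species, parasitic, hosts, Sa, CA,
#' CaCO3, nest_type, source`. `parasitic` is logical (or 0/1);
#' `hosts` is a `;`-separated list of host species for parasitic eggs
#' (empty otherwise); trait columns may be empty for unmeasured eggs.
#'
#' @param file Path to the CSV.
#' @param strict If `TRUE`, out-of-range trait values abort; otherwise the
#'   offending records are dropped with a warning (see [validate_eggs()]).
#' @return A validated egg-table `data.frame`.
#' @export
read_eggs <- function(file, strict = FALSE) {
  if (!file.exists(file)) stop("egg table not found: ", file, call. = FALSE)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_eggs(df, strict = strict)
}

#' Write an egg-level trait table
#' @param eggs Egg-table `data.frame`.
#' @param file Output CSV path.
#' @export
write_eggs <- function(eggs, file) {
  utils::write.csv(eggs[, intersect(egg_columns, names(eggs)), drop = FALSE],
                   file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' Validate an egg-level trait table
#'
#' Structural violations (missing columns, host listed for a non-parasitic
#' egg, duplicated egg ids) always abort. Range violations (Sa <= 0, CA
#' outside (0, 180), CaCO3 outside `[0, 100]`) abort when `strict = TRUE`
#' and are otherwise dropped record-by-record with a warning naming each
#' dropped egg and the reason.
#'
#' @param eggs A `data.frame` with at least `egg_id`, `species`,
#'   `parasitic`; optional `hosts`, `Sa`, `CA`, `CaCO3`, `nest_type`,
#'   `source` (missing optional columns are added as `NA`).
#' @param strict Abort on range violations instead of dropping.
#' @return The validated (possibly filtered) `data.frame`.
#' @export
validate_eggs <- function(eggs, strict = FALSE) {
  need <- c("egg_id", "species", "parasitic")
  missing <- setdiff(need, names(eggs))
  if (length(missing))
    stop("egg table lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in setdiff(egg_columns, names(eggs))) eggs[[col]] <- NA
  eggs <- eggs[, egg_columns]
  eggs$egg_id <- as.character(eggs$egg_id)
  eggs$species <- as.character(eggs$species)
  eggs$parasitic <- as.logical(eggs$parasitic)
  eggs$hosts <- as.character(eggs$hosts)
  eggs$hosts[is.na(eggs$hosts) | eggs$hosts == ""] <- NA_character_
  for (col in c("Sa", "CA", "CaCO3")) eggs[[col]] <- as.numeric(eggs[[col]])
  if (anyDuplicated(eggs$egg_id))
    stop("duplicated egg_id values: ",
         paste(unique(eggs$egg_id[duplicated(eggs$egg_id)]), collapse = ", "),
         call. = FALSE)
  if (anyNA(eggs$parasitic))
    stop("parasitic flag must be TRUE/FALSE for every egg", call. = FALSE)
  bad_host <- !eggs$parasitic & !is.na(eggs$hosts)
  if (any(bad_host))
    stop("host species listed for non-parasitic egg(s): ",
         paste(eggs$egg_id[bad_host], collapse = ", "), call. = FALSE)
  reasons <- character(nrow(eggs))
  flag <- function(bad, msg) {
    bad <- which(bad & !nzchar(reasons))
    reasons[bad] <<- msg
  }
  flag(!is.na(eggs$Sa) & eggs$Sa <= 0, "Sa not positive")
  flag(!is.na(eggs$CA) & (eggs$CA <= 0 | eggs$CA >= 180),
       "CA outside (0, 180)")
  flag(!is.na(eggs$CaCO3) & (eggs$CaCO3 < 0 | eggs$CaCO3 > 100),
       "CaCO3 outside [0, 100]")
  bad <- nzchar(reasons)
  if (any(bad)) {
    msg <- paste(sprintf("%s (%s)", eggs$egg_id[bad], reasons[bad]),
                 collapse = "; ")
    if (strict) stop("invalid trait values: ", msg, call. = FALSE)
    warning("dropping ", sum(bad), " egg record(s) with invalid traits: ",
            msg, call. = FALSE)
    eggs <- eggs[!bad, , drop = FALSE]
  }
  rownames(eggs) <- NULL
  eggs
}

split_hosts <- function(hosts) {
  if (is.na(hosts)) return(character(0))
  trimws(strsplit(hosts, ";", fixed = TRUE)[[1]])
}
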
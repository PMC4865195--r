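#' Scoring-function parameter sets
#'
#' A `term_param_set` bundles everything that defines one empirical scoring
#' function: the five term weights (Gauss1, Gauss2, quadratic repulsion,
#' hydrophobic, non-directional H-bond), the shape parameters of each term,
#' the per-type atomic radii, the surface-distance cutoff, the torsion
#' scaling coefficient, and an optional generic m-n Lennard-Jones term for
#' user-defined functions.
#'
#' Two presets ship with the package as editable flat key-value files under
#' `extdata/`: `"vina"` (two-Gaussian steric term) and `"vinardo"`
#' (single-Gaussian steric term, `w2 = 0`, hydrophobic onset at contact,
#' revised C/N/O radii). All distances are in Angstrom; weighted energies are
#' on the kcal/mol-like affinity scale the presets were fitted on.
#'
#' @param name `"vina"`, `"vinardo"`, or a path to a parameter file in the
#'   same flat `key value` format.
#' @return An object of class `term_param_set`: a list with elements
#'   `name`, `weights` (named: gauss1, gauss2, repulsion, hydrophobic,
#'   hbond), `gauss1`/`gauss2` (each `c(o =, s =)`), `gauss2_enabled`,
#'   `hydrophobic` (`c(p1 =, p2 =)`), `hbond` (`c(h1 =)`), `lj` (`NULL` or
#'   `list(m, n, weight)`), `radii` (named vector keyed by radius class),
#'   `cutoff`, `torsion_coeff`.
#' @examples
#' ps <- scoring_params("vinardo")
#' ps$weights
#' ps$radii[["CA"]]
#' @export
scoring_params <- function(name = "vinardo") {
  stopifnot(is.character(name), length(name) == 1L)
  path <- if (name %in% c("vina", "vinardo")) {
    system.file("extdata", paste0(name, ".params"), package = "dockscore",
                mustWork = TRUE)
  } else {
    name
  }
  read_param_set(path)
}

#' Read a scoring-function definition file
#'
#' Parses the flat `key value` format used by the shipped `vina.params` and
#' `vinardo.params` files. Lines starting with `#` are comments. Radii are
#' given as `radius_<class>` keys where the class is `C`, `CA` (aromatic
#' carbon), `N`, `O`, ..., `Met` (any metal). An optional Lennard-Jones term
#' is declared with `lj_m`, `lj_n` and `lj_weight`.
#'
#' @param path file path.
#' @return A `term_param_set`; see [scoring_params()].
#' @export
read_param_set <- function(path) {
  if (!file.exists(path)) {
    stop("parameter file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- lengths(toks) != 2L
  if (any(bad)) {
    stop("malformed parameter line: ", lines[which(bad)[1L]], call. = FALSE)
  }
  kv <- stats::setNames(vapply(toks, `[`, "", 2L), vapply(toks, `[`, "", 1L))

  num <- function(key, default = NULL) {
    if (key %in% names(kv)) {
      x <- suppressWarnings(as.numeric(kv[[key]]))
      if (is.na(x)) stop("non-numeric value for ", key, call. = FALSE)
      x
    } else if (!is.null(default)) default
    else stop("missing required parameter: ", key, call. = FALSE)
  }
  flag <- function(key, default) {
    if (key %in% names(kv)) tolower(kv[[key]]) %in% c("true", "1", "yes")
    else default
  }

  radii_keys <- grep("^radius_", names(kv), value = TRUE)
  radii <- vapply(radii_keys, num, 0)
  names(radii) <- sub("^radius_", "", radii_keys)

  gauss2_enabled <- flag("gauss2_enabled", "weight_gauss2" %in% names(kv) &&
                           num("weight_gauss2") != 0)
  lj <- NULL
  if ("lj_weight" %in% names(kv)) {
    lj <- list(m = num("lj_m"), n = num("lj_n"), weight = num("lj_weight"))
  }

  ps <- structure(list(
    name = if ("name" %in% names(kv)) kv[["name"]] else "custom",
    weights = c(gauss1 = num("weight_gauss1"),
                gauss2 = num("weight_gauss2", 0),
                repulsion = num("weight_repulsion"),
                hydrophobic = num("weight_hydrophobic"),
                hbond = num("weight_hbond")),
    gauss1 = c(o = num("gauss1_offset", 0), s = num("gauss1_width")),
    gauss2 = if (gauss2_enabled) {
      c(o = num("gauss2_offset"), s = num("gauss2_width"))
    },
    gauss2_enabled = gauss2_enabled,
    hydrophobic = c(p1 = num("hydrophobic_p1"), p2 = num("hydrophobic_p2")),
    hbond = c(h1 = num("hbond_h1")),
    lj = lj,
    radii = radii,
    cutoff = num("cutoff", 8),
    torsion_coeff = num("torsion_coeff", 0.05846)
  ), class = "term_param_set")
  validate_param_set(ps)
}

#' @rdname read_param_set
#' @param ps a `term_param_set`.
#' @export
validate_param_set <- function(ps) {
  stopifnot(inherits(ps, "term_param_set"))
  if (ps$gauss1[["s"]] <= 0) stop("gauss1 width must be > 0", call. = FALSE)
  if (ps$gauss2_enabled && ps$gauss2[["s"]] <= 0) {
    stop("gauss2 width must be > 0", call. = FALSE)
  }
  if (ps$hydrophobic[["p1"]] >= ps$hydrophobic[["p2"]]) {
    stop("hydrophobic onset p1 must be < offset p2", call. = FALSE)
  }
  if (ps$hbond[["h1"]] >= 0) stop("hbond onset h1 must be < 0", call. = FALSE)
  if (!is.null(ps$lj) && ps$lj$m >= ps$lj$n) {
    stop("Lennard-Jones exponents require m < n", call. = FALSE)
  }
  if (any(ps$radii <= 0)) stop("atomic radii must be > 0", call. = FALSE)
  if (ps$cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  if (ps$torsion_coeff < 0) {
    stop("torsion coefficient must be >= 0", call. = FALSE)
  }
  invisible(ps)
}

#' Write a parameter set back to the flat key-value format
#'
#' @param ps a `term_param_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_param_set <- function(ps, path) {
  validate_param_set(ps)
  fmt <- function(x) formatC(x, format = "fg", digits = 15)
  out <- c(
    paste("name", ps$name),
    paste("weight_gauss1", fmt(ps$weights[["gauss1"]])),
    paste("weight_gauss2", fmt(ps$weights[["gauss2"]])),
    paste("weight_repulsion", fmt(ps$weights[["repulsion"]])),
    paste("weight_hydrophobic", fmt(ps$weights[["hydrophobic"]])),
    paste("weight_hbond", fmt(ps$weights[["hbond"]])),
    paste("gauss1_offset", fmt(ps$gauss1[["o"]])),
    paste("gauss1_width", fmt(ps$gauss1[["s"]])),
    paste("gauss2_enabled", if (ps$gauss2_enabled) "true" else "false"),
    if (ps$gauss2_enabled) paste("gauss2_offset", fmt(ps$gauss2[["o"]])),
    if (ps$gauss2_enabled) paste("gauss2_width", fmt(ps$gauss2[["s"]])),
    paste("hydrophobic_p1", fmt(ps$hydrophobic[["p1"]])),
    paste("hydrophobic_p2", fmt(ps$hydrophobic[["p2"]])),
    paste("hbond_h1", fmt(ps$hbond[["h1"]])),
    if (!is.null(ps$lj)) paste("lj_m", fmt(ps$lj$m)),
    if (!is.null(ps$lj)) paste("lj_n", fmt(ps$lj$n)),
    if (!is.null(ps$lj)) paste("lj_weight", fmt(ps$lj$weight)),
    paste("cutoff", fmt(ps$cutoff)),
    paste("torsion_coeff", fmt(ps$torsion_coeff)),
    paste(paste0("radius_", names(ps$radii)), vapply(ps$radii, fmt, ""))
  )
  writeLines(out, path)
  invisible(path)
}

#' Override one parameter of a parameter set
#'
#' `key` uses the same vocabulary as the parameter files
#' (`"weight_gauss1"`, `"gauss1_width"`, `"hydrophobic_p2"`, `"radius_N"`,
#' `"cutoff"`, `"torsion_coeff"`, ...), which is also the vocabulary of the
#' training-screen grid axes.
#'
#' @param ps a `term_param_set`.
#' @param key parameter name.
#' @param value numeric value.
#' @return the modified `term_param_set`.
#' @export
set_param <- function(ps, key, value) {
  stopifnot(inherits(ps, "term_param_set"), is.numeric(value),
            length(value) == 1L)
  wmap <- c(weight_gauss1 = "gauss1", weight_gauss2 = "gauss2",
            weight_repulsion = "repulsion",
            weight_hydrophobic = "hydrophobic", weight_hbond = "hbond")
  if (key %in% names(wmap)) {
    ps$weights[[wmap[[key]]]] <- value
    if (key == "weight_gauss2" && value != 0 && !ps$gauss2_enabled) {
      ps$gauss2_enabled <- TRUE
      if (is.null(ps$gauss2)) ps$gauss2 <- c(o = 3, s = 2)
    }
  } else if (key == "gauss1_offset") ps$gauss1[["o"]] <- value
  else if (key == "gauss1_width") ps$gauss1[["s"]] <- value
  else if (key == "gauss2_offset") ps$gauss2[["o"]] <- value
  else if (key == "gauss2_width") ps$gauss2[["s"]] <- value
  else if (key == "hydrophobic_p1") ps$hydrophobic[["p1"]] <- value
  else if (key == "hydrophobic_p2") ps$hydrophobic[["p2"]] <- value
  else if (key == "hbond_h1") ps$hbond[["h1"]] <- value
  else if (key == "cutoff") ps$cutoff <- value
  else if (key == "torsion_coeff") ps$torsion_coeff <- value
  else if (startsWith(key, "radius_")) {
    ps$radii[[sub("^radius_", "", key)]] <- value
  } else stop("unknown parameter key: ", key, call. = FALSE)
  ps
}

#' @export
print.term_param_set <- function(x, ...) {
  cat("<term_param_set>", x$name, "\n")
  cat("  weights:    ", paste(names(x$weights),
                              signif(x$weights, 6), sep = "=",
                              collapse = "  "), "\n")
  cat("  gauss1:      o=", x$gauss1[["o"]], " s=", x$gauss1[["s"]],
      if (x$gauss2_enabled) {
        paste0("   gauss2: o=", x$gauss2[["o"]], " s=", x$gauss2[["s"]])
      } else "   gauss2: disabled", "\n", sep = "")
  cat("  hydrophobic: p1=", x$hydrophobic[["p1"]], " p2=",
      x$hydrophobic[["p2"]], "   hbond: h1=", x$hbond[["h1"]], "\n", sep = "")
  if (!is.null(x$lj)) {
    cat("  lj:          m=", x$lj$m, " n=", x$lj$n, " weight=", x$lj$weight,
        "\n", sep = "")
  }
  cat("  radii:      ", paste(names(x$radii), x$radii, sep = "=",
                              collapse = "  "), "\n")
  cat("  cutoff:     ", x$cutoff, "A   torsion_coeff:", x$torsion_coeff, "\n")
  invisible(x)
}
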
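# Model parameter handling: construction, validation, fixtures, YAML i/o.

# Canonical field order.  All rates are per day; see ?parameter_set for units.
.param_fields <- c(
  "a", "a1", "b", "c", "c1", "d", "e", "f", "g", "g_i", "h", "j", "k",
  "K_T", "K_N", "K_L", "K_C", "l", "m", "p", "p_i", "q", "r1", "r2", "s",
  "u", "alpha", "alpha1", "alpha2", "beta", "beta1", "beta2", "gamma",
  "mu1", "mu_i", "delta2")

#' Create a model parameter set
#'
#' Bundles the 36 rate and saturation constants of the tumor-immune model
#' for one patient.  All parameters must be strictly positive.
#'
#' @param ... named parameter values.  Required names: `a` (tumor growth
#'   rate, day^-1), `a1` (half-saturation of cytokine tumor kill, cells),
#'   `b` (inverse tumor carrying capacity, cell^-1), `c` (NK tumor kill
#'   rate, cell^-1 day^-1), `c1` (maximum cytokine tumor kill, cell day^-1),
#'   `d` (saturation level of the CD8+ T lysis fraction, day^-1), `e`
#'   (fraction of circulating lymphocytes becoming NK cells, day^-1), `f`
#'   (NK death rate, day^-1), `g` (maximum NK recruitment, day^-1), `g_i`
#'   (steepness of CD8+ T recruitment by IL-2, cell^2), `h` (steepness of
#'   NK recruitment, cell^2), `j` (maximum CD8+ T recruitment, day^-1), `k`
#'   (steepness of CD8+ T recruitment, cell^2), `K_T`, `K_N`, `K_L`, `K_C`
#'   (fractional chemotherapy kill of tumor/NK/CD8+/lymphocytes, day^-1),
#'   `l` (exponent of the lysis fraction, dimensionless), `m` (CD8+ T death
#'   rate, day^-1), `p` (NK inactivation by tumor, cell^-1 day^-1), `p_i`
#'   (maximum CD8+ T recruitment by IL-2, day^-1), `q` (CD8+ T inactivation
#'   by tumor, cell^-1 day^-1), `r1`, `r2` (CD8+ T stimulation by NK-lysed
#'   debris / by lymphocyte-tumor interaction, cell^-1 day^-1), `s`
#'   (steepness of the lysis fraction, dimensionless), `u` (NK regulation
#'   of CD8+ T cells, cell^-2 day^-1), `alpha` (lymphocyte source,
#'   cell day^-1), `alpha1` (half-saturation of CD4+ T production, cells),
#'   `alpha2` (half-saturation of IL-2 production, cells), `beta`
#'   (lymphocyte turnover, day^-1), `beta1` (maximum CD4+ T production,
#'   cell day^-1), `beta2` (maximum IL-2 production, cell^-1 day^-1),
#'   `gamma` (chemotherapy drug decay, day^-1), `mu1` (CD4+ T death rate,
#'   day^-1), `mu_i` (IL-2 decay rate, day^-1), `delta2` (CD4+ T loss by
#'   tumor interaction, cell^-1 day^-1).
#' @param label free-text label for the set (e.g. `"patient1"`).
#'
#' @return An object of class `parameter_set`: a named list of the 36
#'   values plus a `label` attribute.
#' @seealso [patient_params()] for the two bundled reference patients.
#' @export
parameter_set <- function(..., label = "custom") {
  vals <- list(...)
  if (length(vals) == 1L && is.list(vals[[1L]]) && is.null(names(vals)))
    vals <- vals[[1L]]
  vals$label <- NULL
  missing <- setdiff(.param_fields, names(vals))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(vals), .param_fields)
  if (length(extra))
    stop("unknown parameters: ", paste(extra, collapse = ", "))
  out <- lapply(vals[.param_fields], as.numeric)
  bad <- vapply(out, function(x)
    length(x) != 1L || !is.finite(x) || x <= 0, logical(1L))
  if (any(bad))
    stop("parameters must be single strictly positive finite numbers: ",
         paste(.param_fields[bad], collapse = ", "))
  structure(out, label = as.character(label)[1L], class = "parameter_set")
}

#' Bundled reference patient parameter sets
#'
#' Returns one of the two reference human parameter sets shipped with the
#' package (`"patient1"`, `"patient2"`).  The sets are read from the YAML
#' fixtures under `inst/extdata` so that the on-disk serialization is the
#' single source of truth.
#'
#' @param label `"patient1"` or `"patient2"`.
#' @return A [parameter_set].
#' @export
patient_params <- function(label = c("patient1", "patient2")) {
  label <- match.arg(label)
  path <- system.file("extdata", paste0(label, ".yaml"),
                      package = "tumorimmune", mustWork = TRUE)
  read_parameter_set(path)
}

#' Read / write a parameter set as YAML
#'
#' Flat key-to-value mapping; keys are the ASCII parameter names used by
#' [parameter_set()] plus an optional `label`.
#'
#' @param path file path.
#' @return `read_parameter_set` returns a [parameter_set];
#'   `write_parameter_set` returns `path` invisibly.
#' @export
read_parameter_set <- function(path) {
  vals <- yaml::read_yaml(path)
  label <- if (is.null(vals$label)) "unnamed" else vals$label
  vals$label <- NULL
  parameter_set(vals, label = label)
}

#' @rdname read_parameter_set
#' @param params a [parameter_set].
#' @export
write_parameter_set <- function(params, path) {
  stopifnot(inherits(params, "parameter_set"))
  out <- c(list(label = attr(params, "label")), unclass(params))
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Replace one parameter value
#'
#' Used by the bifurcation sweep to substitute a single constant.
#'
#' @param params a [parameter_set].
#' @param name parameter field name.
#' @param value new (strictly positive) value.
#' @return The modified [parameter_set].
#' @export
set_param <- function(params, name, value) {
  stopifnot(inherits(params, "parameter_set"))
  if (!name %in% .param_fields) stop("unknown parameter: ", name)
  if (!is.finite(value) || value <= 0)
    stop("parameter values must be strictly positive")
  params[[name]] <- as.numeric(value)
  params
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Tumor-immune model parameter set:", attr(x, "label"), "\n")
  v <- unlist(unclass(x))
  print(noquote(format(v, digits = 6, scientific = TRUE)))
  invisible(x)
}
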
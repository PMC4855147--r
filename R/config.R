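#' Read a pipeline configuration file
#'
#' YAML key-value config carrying thresholds and masks used across the
#' pipeline stages: `min_frequency` (allele-candidate threshold),
#' `max_tag_mismatch`, `max_primer_mismatch`, `mainland_min_age`,
#' `island_max_age`, `abr_mask` (codon indices), `retention_threshold`,
#' and simulator parameters (`mu`, `N_anc`, `bottleneck_start`,
#' `bottleneck_generations`, `generation_years`). Keys absent from the
#' file keep their defaults.
#'
#' @param path YAML file; NULL returns the defaults.
#' @return named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    min_frequency = 0.05,
    max_tag_mismatch = 1,
    max_primer_mismatch = 1,
    mainland_min_age = 13000,
    island_max_age = 10000,
    abr_mask = integer(),
    retention_threshold = 0.63,
    mu = 1e-7,
    N_anc = 1e5,
    bottleneck_start = 12000,
    bottleneck_generations = 5,
    generation_years = 31)
  if (is.null(path)) return(defaults)
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading config files requires the 'yaml' package")
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "))
  utils::modifyList(defaults, user[intersect(names(user),
                                             names(defaults))])
}
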
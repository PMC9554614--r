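#' Catalogue of ready-made simulation scenarios
#'
#' The package ships the protocols of its reference experiments as flat
#' config files (see [read_config()]) under
#' `system.file("extdata", "scenarios", package = "cleftsim")`, so they are
#' human-diffable rather than buried in code. Keys that a scenario does not
#' set fall back to the standard defaults.
#'
#' @return data.frame with `name` and `description`.
#' @examples
#' list_scenarios()
#' @export
list_scenarios <- function() {
  dir <- system.file("extdata", "scenarios", package = "cleftsim")
  files <- sort(list.files(dir, pattern = "\\.cfg$"))
  desc <- vapply(files, function(f) {
    cfg <- read_config(file.path(dir, f))
    d <- cfg$extra$description
    if (is.null(d)) "" else d
  }, "")
  data.frame(name = sub("\\.cfg$", "", files), description = unname(desc),
             stringsAsFactors = FALSE)
}

#' @rdname list_scenarios
#' @param name scenario name (one of `list_scenarios()$name`).
#' @return `build_scenario()`: list with `params` (`"cleft_params"`),
#'   `numerics` (`"cleft_numerics"`) and `extra` (scenario flags such as
#'   `fixed_layout`, `frequency_hz`, `n_events`).
#' @export
build_scenario <- function(name) {
  dir <- system.file("extdata", "scenarios", package = "cleftsim")
  path <- file.path(dir, paste0(name, ".cfg"))
  if (!file.exists(path)) {
    valid <- sub("\\.cfg$", "", sort(list.files(dir, pattern = "\\.cfg$")))
    stop("unknown scenario '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  }
  read_config(path)
}
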
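#' JSON pipeline configuration with defaults merging
#'
#' A configuration file has one `general` section (global parameters, e.g.
#' `pixel_size` in Angstrom per voxel and the global `seed`) followed by
#' ordered module sections.  Defaults ship in
#' `inst/extdata/defaults.json`; user values win on merge, general values
#' are visible to every module unless overridden locally, and any user key
#' that is unknown for its module is rejected before anything runs — the
#' whole file is validated up front because a pipeline may execute for
#' hours unattended.
#'
#' @param defaults,user parsed JSON documents (named lists, e.g. from
#'   [jsonlite::read_json()]) or file paths.  `user` must contain a
#'   `general` section; remaining sections are module sections in execution
#'   order.  A module name may carry a `.k` suffix (`"Reconstruct.2"`) to
#'   run the same module twice.
#' @return an object of class `effective_config`: list with `general`,
#'   `modules` (ordered list of `list(name, params)`) and `provenance`
#'   (per module, `"default"` or `"user"` per key).
#' @examples
#' cfg <- merge_config(default_config(),
#'                     list(general = list(pixel_size = 2.62),
#'                          ExtractParticles = list(threshold_sigma = 7)))
#' cfg$modules[[1]]$params$threshold_sigma
#' @export
merge_config <- function(defaults, user) {
  defaults <- load_json_arg(defaults)
  user <- load_json_arg(user)
  if (is.null(user$general)) stop("configuration error: missing general section")
  if (is.null(defaults$general)) stop("defaults are missing a general section")

  general <- utils::modifyList(defaults$general, user$general)
  bad <- setdiff(names(user$general), names(defaults$general))
  if (length(bad))
    stop("configuration error: unknown general key(s): ",
         paste(bad, collapse = ", "))
  if (!is.numeric(general$pixel_size) || general$pixel_size <= 0)
    stop("configuration error: general.pixel_size must be > 0")

  module_names <- setdiff(names(user), "general")
  modules <- vector("list", length(module_names))
  provenance <- list(general = stats::setNames(
    ifelse(names(general) %in% names(user$general), "user", "default"),
    names(general)))
  for (i in seq_along(module_names)) {
    full <- module_names[i]
    base <- sub("\\.[0-9]+$", "", full)
    if (is.null(defaults[[base]]))
      stop("configuration error: unknown module '", base, "'")
    def <- defaults[[base]]
    usr <- user[[full]]
    if (is.null(usr)) usr <- list()
    if (!is.list(usr)) stop("configuration error: section '", full,
                            "' is not a parameter mapping")
    bad <- setdiff(names(usr), c(names(def), names(general)))
    if (length(bad))
      stop("configuration error: unknown key(s) for module '", base, "': ",
           paste(bad, collapse = ", "))
    for (k in intersect(names(usr), names(def))) {
      if (!same_json_type(def[[k]], usr[[k]]))
        stop("configuration error: type mismatch for ", base, ".", k,
             " (default is ", class(def[[k]])[1], ")")
    }
    # precedence: module defaults < general section < user module section
    params <- def
    for (k in names(general)) params[[k]] <- general[[k]]
    params <- utils::modifyList(params, usr)
    provenance[[full]] <- stats::setNames(
      ifelse(names(params) %in% names(usr), "user", "default"), names(params))
    modules[[i]] <- list(name = base, section = full, params = params)
  }
  structure(list(general = general, modules = modules,
                 provenance = provenance),
            class = "effective_config")
}

same_json_type <- function(a, b) {
  if (is.numeric(a) && is.numeric(b)) return(TRUE)
  if (is.character(a) && is.character(b)) return(TRUE)
  if (is.logical(a) && is.logical(b)) return(TRUE)
  if (is.list(a) && is.list(b)) return(TRUE)
  # defaults may use NULL to mean "optional, any scalar"
  is.null(a) || is.null(b)
}

load_json_arg <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("no such config file: ", x)
    x <- jsonlite::read_json(x, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  }
  if (!is.list(x)) stop("configuration must be a JSON object")
  x
}

#' @rdname merge_config
#' @export
default_config <- function() {
  path <- system.file("extdata", "defaults.json", package = "tomosta")
  load_json_arg(path)
}

# Re-expressing an effective config as a user document for idempotence.
config_as_user <- function(cfg) {
  out <- list(general = cfg$general)
  for (m in cfg$modules) {
    def <- default_config()[[m$name]]
    sec <- m$params[intersect(names(m$params), names(def))]
    sec <- sec[!vapply(sec, is.null, logical(1))]  # NULL means "unset"
    out[[m$section]] <- sec
  }
  out
}
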
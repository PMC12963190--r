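## File formats: CSV datasets (with a JSON provenance sidecar), JSON model
## serialisation, and YAML run configuration.

.tensor_cols <- function(prefix) {
  paste0(prefix, c("11", "22", "33", "23", "13", "12"))
}

#' Write a dataset to CSV
#'
#' One row per record with columns `mode`, `strain`, `rate`, the Voigt
#' components of `C`, `Cdot` and `S`, and `label`. Numbers are written with
#' 17 significant digits so that a read/write round trip is bit-exact. A
#' JSON sidecar (`<path>.json`) records provenance: law, parameters,
#' protocol and noise seed.
#'
#' @param dataset A `"vh_dataset"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "vh_dataset"))
  rows <- lapply(seq_along(dataset$points), function(i) {
    p <- dataset$points[[i]]
    c(voigt(p$C), voigt(p$Cdot), voigt(dataset$S[[i]]))
  })
  num <- do.call(rbind, rows)
  colnames(num) <- c(.tensor_cols("C"), .tensor_cols("Cd"),
                     .tensor_cols("S"))
  df <- data.frame(
    mode = vapply(dataset$points, function(p) attr(p, "mode") %||% NA_character_,
                  character(1)),
    strain = vapply(dataset$points, function(p) attr(p, "strain") %||% NA_real_,
                    numeric(1)),
    rate = vapply(dataset$points, function(p) attr(p, "rate") %||% NA_real_,
                  numeric(1)))
  for (j in colnames(num)) df[[j]] <- format(num[, j], digits = 17,
                                             scientific = TRUE, trim = TRUE)
  df$strain <- format(df$strain, digits = 17, scientific = TRUE, trim = TRUE)
  df$rate <- format(df$rate, digits = 17, scientific = TRUE, trim = TRUE)
  df$label <- dataset$label
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(law = dataset$law, params = dataset$params,
               label = dataset$label,
               protocol = list(mode = dataset$spec$mode,
                               strain = dataset$spec$strain,
                               rates = dataset$spec$rates),
               noise = dataset$noise)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a dataset from CSV
#'
#' Inverse of [write_dataset()]. Deformation states are rebuilt from the
#' stored `(C, Cdot)` tensors; the JSON sidecar, if present, restores
#' provenance metadata.
#'
#' @param path CSV path written by [write_dataset()].
#' @return A `"vh_dataset"`.
#' @export
read_dataset <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  required <- c("mode", "strain", "rate", .tensor_cols("C"),
                .tensor_cols("Cd"), .tensor_cols("S"), "label")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("dataset file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  numcols <- setdiff(required, c("mode", "label"))
  for (j in numcols) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) & df[[j]] != "NA")
    if (length(bad))
      stop("non-numeric value in column '", j, "' at data line ", bad[1],
           " of ", path, call. = FALSE)
    df[[j]] <- v
  }
  points <- lapply(seq_len(nrow(df)), function(i) {
    C <- unvoigt(as.numeric(df[i, .tensor_cols("C")]))
    Cd <- unvoigt(as.numeric(df[i, .tensor_cols("Cd")]))
    pt <- .deformation_point_from_C(C, Cd)
    attr(pt, "mode") <- df$mode[i]
    attr(pt, "strain") <- df$strain[i]
    attr(pt, "rate") <- df$rate[i]
    pt
  })
  S <- lapply(seq_len(nrow(df)), function(i)
    unvoigt(as.numeric(df[i, .tensor_cols("S")])))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
          else NULL
  spec <- if (!is.null(meta$protocol))
    protocol_spec(meta$protocol$mode, meta$protocol$strain,
                  meta$protocol$rates %||% numeric(0))
  else NULL
  structure(list(points = points, S = S, label = df$label[1],
                 law = meta$law %||% NA_character_,
                 params = meta$params, spec = spec,
                 noise = meta$noise),
            class = "vh_dataset")
}

#' Serialise a fitted constitutive model to JSON
#'
#' Stores, per surrogate: kernel name and hyperparameters, per-point noise,
#' the input-standardisation transform, and the full-precision training
#' inputs/outputs -- everything needed to rebuild predictions exactly.
#'
#' @param model A `"constitutive_model"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "constitutive_model"))
  ser <- lapply(model$surrogates, function(s) {
    gp <- s$gp
    list(variant = s$variant, kernel = "matern32",
         theta = as.list(gp$theta), alpha = gp$alpha,
         transform = gp$transform, y_scale = gp$y_scale,
         X = gp$X, Y = gp$Y,
         constrained = gp$constrained,
         n_constraints = gp$n_constraints,
         lml = gp$lml)
  })
  jsonlite::write_json(list(package = "viscogpr", surrogates = ser,
                            rcond = model$rcond),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Restore a fitted constitutive model from JSON
#'
#' @param path JSON path written by [write_model()].
#' @return A `"constitutive_model"` whose predictions match the original.
#' @export
read_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  surrogates <- lapply(seq_along(ser$surrogates), function(i) {
    s <- if (is.data.frame(ser$surrogates)) {
      as.list(ser$surrogates[i, ])
    } else ser$surrogates[[i]]
    variant <- s$variant
    info <- .variant_info[[variant]]
    Xs <- matrix(unlist(s$X), ncol = length(info$inputs))
    Y <- matrix(unlist(s$Y), ncol = length(info$coef))
    theta <- c(sigma_f = as.numeric(s$theta$sigma_f),
               l = as.numeric(s$theta$l))
    tr <- list(center = as.numeric(unlist(s$transform$center)),
               scale = as.numeric(unlist(s$transform$scale)))
    gp <- .gp_finalize(theta, Xs, Y, as.numeric(unlist(s$alpha)), tr,
                       gp_config(), as.numeric(s$lml),
                       y_scale = as.numeric(unlist(s$y_scale)),
                       constrained = isTRUE(s$constrained),
                       n_constraints = as.integer(s$n_constraints %||% 0L))
    structure(list(variant = variant, gp = gp, inputs = info$inputs,
                   coef_names = info$coef, n_train = nrow(Xs)),
              class = "surrogate_model")
  })
  names(surrogates) <- vapply(surrogates, function(s) s$variant, character(1))
  structure(list(surrogates = surrogates, config = gp_config(),
                 rcond = ser$rcond %||% 1e-10),
            class = "constitutive_model")
}

.config_defaults <- function() {
  list(case = "vol",
       seed = 1L,
       restarts = 5L,
       rcond = 1e-10,
       constraint_tol = 1e-8,
       alpha_vol = 1e-4,
       alpha_reference = 1e-5,
       alpha_other = 1e-2,
       include_classical = FALSE,
       noise_sigma_rel = 0,
       out = NULL)
}

#' Load a YAML run configuration
#'
#' Reads a YAML document, applies documented defaults for absent keys, and
#' rejects unknown keys. An empty file yields the all-defaults
#' configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A named list of class `"run_config"`.
#' @export
load_config <- function(path = NULL) {
  defaults <- .config_defaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, user)
  cfg$seed <- as.integer(cfg$seed)
  cfg$restarts <- as.integer(cfg$restarts)
  structure(cfg, class = c("run_config", "list"))
}
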
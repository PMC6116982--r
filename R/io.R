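# ---------------------------------------------------------------------------
# Dataset, draws and configuration I/O. Everything is plain text: datasets
# as long-format CSV (one row per subject x replicate), posterior parameter
# draws as one CSV per chain, spline draws and configurations as JSON.
# ---------------------------------------------------------------------------

DATASET_COLUMNS <- c("subject_id", "replicate", "w_ee", "w_es",
                     "y_ee", "y_es", "gender", "age", "bmi")

#' Write a dataset to CSV
#'
#' Long format with columns subject_id, replicate, w_ee, w_es, y_ee, y_es,
#' gender, age, bmi. If the dataset carries generator truth, a sidecar
#' \code{<path>_truth.csv} with the per-subject latents is written too.
#'
#' @param dataset an \code{eb_dataset}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  n <- nrow(dataset$covariates); J <- ncol(dataset$w_ee)
  long <- data.frame(
    subject_id = rep(dataset$covariates$subject_id, J),
    replicate = rep(seq_len(J), each = n),
    w_ee = as.vector(dataset$w_ee), w_es = as.vector(dataset$w_es),
    y_ee = as.vector(dataset$y_ee), y_es = as.vector(dataset$y_es),
    gender = rep(dataset$covariates$gender, J),
    age = rep(dataset$covariates$age, J),
    bmi = rep(dataset$covariates$bmi, J))
  long <- long[order(long$subject_id, long$replicate), ]
  write.csv(long, path, row.names = FALSE)
  if (!is.null(dataset$truth))
    write.csv(cbind(subject_id = dataset$covariates$subject_id,
                    dataset$truth),
              sub("\\.csv$", "_truth.csv", path), row.names = FALSE)
  invisible(path)
}

#' Read a dataset from CSV
#'
#' Expects the schema written by \code{\link{write_dataset}}; the
#' gold-standard columns \code{w_ee}, \code{w_es} may be absent for
#' calibration-only inputs. Subjects must have equal replicate counts
#' (the models assume a balanced design).
#'
#' @param path CSV path.
#' @return An \code{eb_dataset} (without truth or config).
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path)
  required <- setdiff(DATASET_COLUMNS, c("w_ee", "w_es"))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("dataset is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  num_cols <- intersect(DATASET_COLUMNS, names(df))
  bad <- num_cols[!vapply(df[num_cols], is.numeric, TRUE)]
  if (length(bad))
    stop("non-numeric values in column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  counts <- table(df$subject_id)
  if (length(unique(counts)) != 1)
    stop("unbalanced replicate counts across subjects; the models assume ",
         "a balanced design", call. = FALSE)
  J <- as.integer(counts[1])
  df <- df[order(df$subject_id, df$replicate), ]
  ids <- unique(df$subject_id)
  n <- length(ids)
  first <- df[df$replicate == df$replicate[1] & !duplicated(df$subject_id), ]
  covs <- data.frame(subject_id = ids,
                     gender = first$gender[match(ids, first$subject_id)],
                     age = first$age[match(ids, first$subject_id)],
                     bmi = first$bmi[match(ids, first$subject_id)])
  tomat <- function(col)
    if (col %in% names(df))
      matrix(df[[col]], n, J, byrow = TRUE) else NULL
  structure(list(covariates = covs, truth = NULL,
                 w_ee = tomat("w_ee"), w_es = tomat("w_es"),
                 y_ee = tomat("y_ee"), y_es = tomat("y_es"),
                 config = NULL),
            class = "eb_dataset")
}

#' Write posterior draws to a directory
#'
#' One \code{chain<k>.csv} per chain with a parameter-name header row; for
#' spline models additionally \code{chain<k>_spline.json} with the per-draw
#' knots and coefficients, plus \code{meta.json} (model kind, boundaries,
#' chain configuration) - enough to rebuild the \code{eb_draws} exactly.
#'
#' @param draws an \code{eb_draws}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_draws <- function(draws, dir) {
  stopifnot(inherits(draws, "eb_draws"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (c_id in seq_along(draws$chains)) {
    write.csv(as.data.frame(draws$chains[[c_id]]),
              file.path(dir, sprintf("chain%d.csv", c_id)),
              row.names = FALSE)
    if (!is.null(draws$spline))
      jsonlite::write_json(draws$spline[[c_id]],
                           file.path(dir, sprintf("chain%d_spline.json", c_id)),
                           digits = NA)
  }
  meta <- list(kind = draws$kind, n_chains = length(draws$chains),
               boundary_ee = draws$boundary_ee,
               boundary_es = draws$boundary_es)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read posterior draws written by \code{\link{write_draws}}
#'
#' @param dir directory containing \code{meta.json} and chain files.
#' @return An \code{eb_draws}.
#' @export
read_draws <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  chains <- list(); spline <- list()
  for (c_id in seq_len(meta$n_chains)) {
    chains[[c_id]] <- as.matrix(read.csv(
      file.path(dir, sprintf("chain%d.csv", c_id))))
    sp_path <- file.path(dir, sprintf("chain%d_spline.json", c_id))
    if (file.exists(sp_path)) {
      raw <- jsonlite::read_json(sp_path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
      # empty knot vectors serialise as [] and deserialise as NULL
      spline[[c_id]] <- lapply(raw, lapply,
                               function(v) as.numeric(unlist(v)))
    }
  }
  extra <- if (length(spline))
    list(spline = spline, boundary_ee = meta$boundary_ee,
         boundary_es = meta$boundary_es) else list()
  new_eb_draws(meta$kind, chains, NULL, extra)
}

#' Write a run manifest
#'
#' Records the seed, configuration and package version alongside outputs so
#' a run can be reproduced bit for bit.
#'
#' @param path output JSON path.
#' @param seed root seed used.
#' @param config any serialisable configuration list.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(path, seed, config = NULL) {
  unclassed <- function(x) if (is.list(x)) lapply(unclass(x), unclassed) else x
  jsonlite::write_json(
    list(seed = seed,
         package = "ebmem",
         version = as.character(utils::packageVersion("ebmem")),
         r_version = R.version.string,
         config = unclassed(config)),
    path, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(path)
}
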
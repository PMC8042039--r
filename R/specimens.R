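#' A single specimen's landmark configuration
#'
#' @param specimen_id,group_id character identifiers.
#' @param coords `L x 3` numeric matrix of landmark coordinates (mm).
#'   Rows at missing landmarks may hold `NA`.
#' @param sex one of `"M"`, `"F"`, `"unknown"`.
#' @param missing logical mask of length `L`; defaults to rows of `coords`
#'   containing `NA`.
#' @return An object of class `specimen_config`.
#' @export
specimen_config <- function(specimen_id, group_id, coords,
                            sex = "unknown", missing = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an L x 3 matrix")
  storage.mode(coords) <- "double"
  if (is.null(missing)) missing <- apply(coords, 1, function(r) any(!is.finite(r)))
  missing <- as.logical(missing)
  if (length(missing) != nrow(coords))
    stop("missing mask length must equal the number of landmarks")
  if (any(!is.finite(coords[!missing, , drop = FALSE])))
    stop("non-finite coordinates at landmarks not flagged missing")
  sex <- match.arg(sex, c("M", "F", "unknown"))
  structure(list(specimen_id = as.character(specimen_id),
                 group_id = as.character(group_id),
                 sex = sex, coords = coords, missing = missing),
            class = "specimen_config")
}

#' @export
print.specimen_config <- function(x, ...) {
  cat("Specimen", x$specimen_id, "(group", x$group_id, ", sex", x$sex, "):",
      nrow(x$coords), "landmarks,", sum(x$missing), "missing\n")
  invisible(x)
}

#' Number of missing landmarks
#' @param config a [specimen_config()].
#' @export
n_missing <- function(config) sum(config$missing)

#' Does a specimen exceed the missing-landmark limit?
#'
#' Specimens missing more than `max_missing` landmarks (default 4) are
#' excluded from the analysis rather than imputed.
#'
#' @param config a [specimen_config()].
#' @param max_missing exclusion threshold.
#' @export
is_excluded <- function(config, max_missing = 4L) n_missing(config) > max_missing

#' Flatten / unflatten landmark configurations
#'
#' Flattening is landmark-major: `x1, y1, z1, x2, y2, z2, ...`.
#'
#' @param coords `L x 3` matrix.
#' @return `flatten_coords()` a numeric vector of length `3L`;
#'   `unflatten_coords()` an `L x 3` matrix.
#' @export
flatten_coords <- function(coords) as.vector(t(coords))

#' @rdname flatten_coords
#' @param v numeric vector of length `3L`.
#' @export
unflatten_coords <- function(v) matrix(v, ncol = 3, byrow = TRUE)

# list of configs -> L x 3 x n array (requires complete configs)
configs_to_array <- function(configs) {
  stopifnot(length(configs) >= 1)
  L <- nrow(configs[[1]]$coords)
  arr <- array(NA_real_, c(L, 3, length(configs)),
               dimnames = list(NULL, c("x", "y", "z"),
                               vapply(configs, `[[`, "", "specimen_id")))
  for (i in seq_along(configs)) arr[, , i] <- configs[[i]]$coords
  arr
}

config_meta <- function(configs) {
  data.frame(specimen_id = vapply(configs, `[[`, "", "specimen_id"),
             group_id = vapply(configs, `[[`, "", "group_id"),
             sex = vapply(configs, `[[`, "", "sex"),
             stringsAsFactors = FALSE)
}

#' Read landmark data from a wide CSV file
#'
#' Expected columns: `specimen_id`, `group_id`, `sex`, then
#' `<label>_x`, `<label>_y`, `<label>_z` for every landmark in scheme order.
#' Empty cells mark missing landmarks.
#'
#' @param path CSV file path.
#' @param scheme a [landmark_scheme()]; column order is validated against it.
#' @return list of [specimen_config()] objects.
#' @export
read_landmark_csv <- function(path, scheme) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("specimen_id", "group_id", "sex", coordinate_labels(scheme))
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("landmark CSV lacks column(s): ", paste(utils::head(miss, 5), collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    v <- as.numeric(df[i, coordinate_labels(scheme)])
    specimen_config(df$specimen_id[i], df$group_id[i],
                    unflatten_coords(v), sex = df$sex[i])
  })
}

#' Write landmark data to a wide CSV file
#'
#' @param configs list of [specimen_config()] objects.
#' @param scheme a [landmark_scheme()].
#' @param path output CSV path.
#' @export
write_landmark_csv <- function(configs, scheme, path) {
  rows <- lapply(configs, function(cf) {
    v <- flatten_coords(cf$coords)
    v[rep(cf$missing, each = 3)] <- NA_real_
    cbind(data.frame(specimen_id = cf$specimen_id, group_id = cf$group_id,
                     sex = cf$sex, stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(v, coordinate_labels(scheme)))))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read landmark data from a TPS-format file
#'
#' Supports 3D blocks (`LM3=<n>` followed by n coordinate lines) with `ID=`
#' keys; `IMAGE=` and `SCALE=` lines are ignored. The conventional
#' `9999 9999 9999` triple encodes a missing landmark and is converted to the
#' missing mask.
#'
#' @param path TPS file path.
#' @param scheme a [landmark_scheme()] (validates landmark count).
#' @param group_id,sex defaults applied to every specimen in the file (the
#'   TPS dialect carries neither).
#' @return list of [specimen_config()] objects.
#' @export
read_tps <- function(path, scheme, group_id = "unknown", sex = "unknown") {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  configs <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!grepl("^LM3=", lines[i], ignore.case = TRUE))
      stop("expected LM3= block at line ", i)
    L <- as.integer(sub("^LM3=", "", lines[i], ignore.case = TRUE))
    if (L != n_landmarks(scheme))
      stop("TPS block has ", L, " landmarks; scheme expects ", n_landmarks(scheme))
    xyz <- t(vapply(lines[i + seq_len(L)],
                    function(s) as.numeric(strsplit(s, "[[:space:]]+")[[1]][1:3]),
                    numeric(3)))
    rownames(xyz) <- NULL
    i <- i + L + 1
    id <- sprintf("tps_%d", length(configs) + 1)
    while (i <= length(lines) && !grepl("^LM3=", lines[i], ignore.case = TRUE)) {
      if (grepl("^ID=", lines[i], ignore.case = TRUE))
        id <- sub("^ID=", "", lines[i], ignore.case = TRUE)
      i <- i + 1
    }
    miss <- rowSums(xyz == 9999) == 3
    xyz[miss, ] <- NA_real_
    configs[[length(configs) + 1]] <-
      specimen_config(id, group_id, xyz, sex = sex, missing = miss)
  }
  configs
}
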
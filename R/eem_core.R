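# EEM data model: wavelength grids, single scans, stacks, fold/unfold.
#
# Orientation convention used everywhere in this package: an EEM intensity
# matrix is [emission x excitation] -- emission varies along rows -- matching
# the usual contour-plot presentation of EEM data.

#' Construct a wavelength grid
#'
#' An inclusive arithmetic sequence of wavelengths in nanometres, used for
#' the excitation and emission axes of an EEM. Both endpoints are included,
#' so the grid has `(end - start) / step + 1` points.
#'
#' @param start first wavelength (nm).
#' @param end last wavelength (nm); must satisfy `end >= start` and
#'   `(end - start)` exactly divisible by `step`.
#' @param step grid spacing (nm), strictly positive.
#' @return An object of class `wl_grid`: a numeric vector of wavelengths with
#'   `start`, `end` and `step` attributes.
#' @examples
#' length(make_grid(250, 450, 5))  # 41 excitation wavelengths
#' length(make_grid(250, 600, 1))  # 351 emission wavelengths
#' @export
make_grid <- function(start, end, step) {
  if (!is.numeric(start) || !is.numeric(end) || !is.numeric(step))
    stopf("grid definition error: start, end, step must be numeric")
  if (step <= 0) stopf("grid definition error: step must be > 0 (got %g)", step)
  if (end < start) stopf("grid definition error: end (%g) < start (%g)", end, start)
  n_steps <- (end - start) / step
  if (!is_whole(n_steps))
    stopf("grid definition error: (end - start) = %g not divisible by step = %g",
          end - start, step)
  values <- start + step * seq.int(0L, round(n_steps))
  structure(values, start = start, end = end, step = step, class = "wl_grid")
}

#' @export
print.wl_grid <- function(x, ...) {
  cat(sprintf("<wl_grid> %g-%g nm, step %g nm (%d points)\n",
              attr(x, "start"), attr(x, "end"), attr(x, "step"), length(x)))
  invisible(x)
}

grid_equal <- function(a, b) {
  length(a) == length(b) && all(abs(as.numeric(a) - as.numeric(b)) < 1e-9)
}

#' Construct a single EEM scan
#'
#' @param intensity numeric matrix `[emission x excitation]`; `NA` marks a
#'   missing (for example scatter-excised) cell. At least one entry must be
#'   observed and observed entries must be finite.
#' @param ex_grid,em_grid [make_grid()] objects for the excitation and
#'   emission axes.
#' @param sample_id character scalar identifying the sample.
#' @param replicate_id integer analytical replicate number.
#' @return An object of class `eem`.
#' @export
eem <- function(intensity, ex_grid, em_grid, sample_id = "sample",
                replicate_id = 1L) {
  if (!inherits(ex_grid, "wl_grid") || !inherits(em_grid, "wl_grid"))
    stopf("ex_grid and em_grid must be wl_grid objects")
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(em_grid) || ncol(intensity) != length(ex_grid))
    stopf("intensity shape (%d x %d) does not match grids (em %d x ex %d)",
          nrow(intensity), ncol(intensity), length(em_grid), length(ex_grid))
  obs <- !is.na(intensity)
  if (!any(obs)) stopf("EEM has no observed intensities")
  if (any(!is.finite(intensity[obs])))
    stopf("EEM contains non-finite observed intensities")
  structure(list(intensity = intensity, ex_grid = ex_grid, em_grid = em_grid,
                 sample_id = as.character(sample_id),
                 replicate_id = as.integer(replicate_id)),
            class = "eem")
}

#' @export
print.eem <- function(x, ...) {
  cat(sprintf("<eem> %s (rep %d): %d em x %d ex, %d missing cells\n",
              x$sample_id, x$replicate_id, nrow(x$intensity),
              ncol(x$intensity), sum(is.na(x$intensity))))
  invisible(x)
}

#' Read an EEM from a matrix-dialect CSV file
#'
#' The dialect is strict: UTF-8, comma separated, `.` decimal; first row
#' holds the excitation wavelengths (first cell blank), first column the
#' emission wavelengths, and the body the intensities. Empty cells are
#' missing values. Headers must form valid even-spaced ascending grids.
#'
#' @param path file to read.
#' @param sample_id,replicate_id identifiers attached to the returned scan.
#' @return An [eem()] object.
#' @seealso [write_eem_csv()], its exact inverse for finite-valued EEMs.
#' @export
read_eem_csv <- function(path, sample_id = NULL, replicate_id = 1L) {
  if (!file.exists(path)) stopf("EEM file not found: %s", path)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (nrow(raw) < 2L || ncol(raw) < 2L)
    stopf("format error in %s: need a header row, a header column and a body", path)
  parse_num <- function(x, what, idx) {
    x[x == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad))
      stopf("format error in %s: non-numeric %s at position %d ('%s')",
            path, what, idx[bad[1]], x[bad[1]])
    out
  }
  ex_vals <- parse_num(as.character(raw[1L, -1L]), "excitation header (column)",
                       seq_len(ncol(raw) - 1L) + 1L)
  em_vals <- parse_num(as.character(raw[-1L, 1L]), "emission header (row)",
                       seq_len(nrow(raw) - 1L) + 1L)
  if (anyNA(ex_vals) || anyNA(em_vals))
    stopf("format error in %s: blank wavelength header cell", path)
  grid_from_header <- function(v, axis) {
    if (length(v) == 1L) return(make_grid(v, v, 1))
    d <- diff(v)
    if (any(d <= 0)) stopf("format error in %s: %s header not ascending", path, axis)
    if (max(d) - min(d) > 1e-6)
      stopf("format error in %s: %s header step not constant (%g vs %g)",
            path, axis, min(d), max(d))
    make_grid(v[1L], v[length(v)], d[1L])
  }
  ex_grid <- grid_from_header(ex_vals, "excitation")
  em_grid <- grid_from_header(em_vals, "emission")
  body <- as.matrix(raw[-1L, -1L, drop = FALSE])
  body[body == ""] <- NA_character_
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(!is.na(body) & is.na(num), arr.ind = TRUE)
  if (nrow(bad))
    stopf("format error in %s: non-numeric intensity at row %d, column %d",
          path, bad[1L, 1L] + 1L, bad[1L, 2L] + 1L)
  eem(num, ex_grid, em_grid,
      sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)),
      replicate_id = replicate_id)
}

#' Write an EEM to a matrix-dialect CSV file
#'
#' Inverse of [read_eem_csv()]; finite intensities round-trip bit-identically
#' (full `%.17g` precision), missing cells are written as empty fields.
#'
#' @param x an [eem()] object.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_eem_csv <- function(x, path) {
  stopifnot(inherits(x, "eem"))
  fmt <- function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- ""
    out
  }
  header <- paste0(",", paste(fmt(as.numeric(x$ex_grid)), collapse = ","))
  rows <- vapply(seq_len(nrow(x$intensity)), function(i) {
    paste0(fmt(as.numeric(x$em_grid)[i]), ",",
           paste(fmt(x$intensity[i, ]), collapse = ","))
  }, character(1))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Assemble EEM scans into a stack
#'
#' All scans must share identical excitation and emission grids and carry
#' unique `(sample_id, replicate_id)` pairs. The stack is the package's
#' three-way array: excitation x emission x scan (for the full study design,
#' 41 x 351 x 624).
#'
#' @param eems list of [eem()] objects.
#' @param reference optional named numeric vector or data frame
#'   (`sample_id`, `retinol_iu_dl`) of reference retinol concentrations in
#'   IU/dl; must cover every sample in the stack when supplied.
#' @return An object of class `eem_stack`.
#' @export
build_stack <- function(eems, reference = NULL) {
  if (inherits(eems, "eem")) eems <- list(eems)
  if (!length(eems)) stopf("cannot build a stack from zero EEMs")
  if (!all(vapply(eems, inherits, logical(1), "eem")))
    stopf("all elements must be eem objects")
  ref_grid_ex <- eems[[1L]]$ex_grid
  ref_grid_em <- eems[[1L]]$em_grid
  mismatched <- vapply(eems, function(e) {
    !grid_equal(e$ex_grid, ref_grid_ex) || !grid_equal(e$em_grid, ref_grid_em)
  }, logical(1))
  if (any(mismatched))
    stopf("grid mismatch for sample(s): %s",
          paste(unique(vapply(eems[mismatched], `[[`, character(1), "sample_id")),
                collapse = ", "))
  keys <- vapply(eems, function(e) paste(e$sample_id, e$replicate_id, sep = "\r"),
                 character(1))
  if (anyDuplicated(keys))
    stopf("duplicate (sample_id, replicate_id): %s",
          gsub("\r", "/", keys[duplicated(keys)][1L]))
  if (!is.null(reference)) {
    if (is.data.frame(reference)) {
      stopifnot(all(c("sample_id", "retinol_iu_dl") %in% names(reference)))
      reference <- stats::setNames(as.numeric(reference$retinol_iu_dl),
                                   as.character(reference$sample_id))
    }
    ids <- unique(vapply(eems, `[[`, character(1), "sample_id"))
    missing_ref <- setdiff(ids, names(reference))
    if (length(missing_ref))
      stopf("reference table lacks sample(s): %s",
            paste(missing_ref, collapse = ", "))
  }
  structure(list(eems = eems, reference = reference,
                 ex_grid = ref_grid_ex, em_grid = ref_grid_em),
            class = "eem_stack")
}

#' @export
print.eem_stack <- function(x, ...) {
  d <- stack_dims(x)
  cat(sprintf("<eem_stack> %d scans of %d samples (%d ex x %d em)%s\n",
              d[["sample"]], length(unique(sample_ids(x))),
              d[["ex"]], d[["em"]],
              if (is.null(x$reference)) "" else ", with reference values"))
  invisible(x)
}

#' @export
length.eem_stack <- function(x) length(x$eems)

#' Stack dimensions in excitation x emission x scan order
#' @param stack an [build_stack()] object.
#' @return Named integer vector `c(ex=, em=, sample=)`.
#' @export
stack_dims <- function(stack) {
  c(ex = length(stack$ex_grid), em = length(stack$em_grid),
    sample = length(stack$eems))
}

#' Sample identifiers of the scans in stack order
#' @param stack an `eem_stack`.
#' @return Character vector, one entry per scan.
#' @export
sample_ids <- function(stack) {
  vapply(stack$eems, `[[`, character(1), "sample_id")
}

#' Reference concentration for every scan in stack order
#' @param stack an `eem_stack` with a reference table; replicate scans
#'   inherit their sample's value.
#' @return Numeric vector (IU/dl), one entry per scan.
#' @export
stack_reference <- function(stack) {
  if (is.null(stack$reference)) stopf("stack carries no reference values")
  unname(stack$reference[sample_ids(stack)])
}

#' Convert a stack to a dense three-way array
#' @param stack an `eem_stack`.
#' @return Numeric array `[em x ex x scan]` with `NA` for missing cells.
#' @export
as_array <- function(stack) {
  stopifnot(inherits(stack, "eem_stack"))
  d <- stack_dims(stack)
  arr <- array(NA_real_, dim = c(d[["em"]], d[["ex"]], d[["sample"]]))
  for (k in seq_along(stack$eems)) arr[, , k] <- stack$eems[[k]]$intensity
  dimnames(arr) <- list(as.character(as.numeric(stack$em_grid)),
                        as.character(as.numeric(stack$ex_grid)), NULL)
  arr
}

#' Average analytical replicates within each sample
#'
#' Collapses the stack to one scan per `sample_id`, taking the entrywise
#' mean over non-missing replicate values; a cell stays missing only when it
#' is missing in every replicate. Idempotent. Sample order follows first
#' appearance in the stack.
#'
#' @param stack an `eem_stack`.
#' @return An `eem_stack` with one scan (replicate_id 1) per sample.
#' @export
average_replicates <- function(stack) {
  stopifnot(inherits(stack, "eem_stack"))
  ids <- sample_ids(stack)
  out <- lapply(unique(ids), function(id) {
    members <- stack$eems[ids == id]
    acc <- matrix(0, nrow(members[[1L]]$intensity), ncol(members[[1L]]$intensity))
    cnt <- acc
    for (m in members) {
      obs <- !is.na(m$intensity)
      acc[obs] <- acc[obs] + m$intensity[obs]
      cnt <- cnt + obs
    }
    avg <- acc / cnt  # 0/0 -> NaN where all replicates missing
    avg[cnt == 0] <- NA_real_
    eem(avg, stack$ex_grid, stack$em_grid, sample_id = id, replicate_id = 1L)
  })
  build_stack(out, reference = stack$reference)
}

#' Unfold a stack into the two-way sample x variable matrix for PLS
#'
#' Columns are ordered excitation-major: all emission wavelengths for the
#' first excitation, then the next excitation, and so on. The accompanying
#' variable map records the `(ex, em)` pair behind every retained column so
#' coefficient and VIP vectors can be refolded into contour maps.
#'
#' @param stack an `eem_stack`.
#' @param missing how to treat cells that are missing in some scan:
#'   `"drop"` (default) removes a column if it is missing in *any* scan
#'   (scatter excision removes the same cells in every scan, so this loses
#'   only excised regions); `"impute"` replaces missing entries by the
#'   column mean over observed scans (columns missing everywhere are still
#'   dropped).
#' @return List with `X` (numeric matrix, rows in stack order, rownames
#'   `sample_id.replicate_id`) and `vmap` (data frame `col`, `ex`, `em`
#'   mapping columns of `X` to grid cells).
#' @export
unfold <- function(stack, missing = c("drop", "impute")) {
  missing <- match.arg(missing)
  d <- stack_dims(stack)
  n_var <- d[["em"]] * d[["ex"]]
  X <- matrix(NA_real_, nrow = d[["sample"]], ncol = n_var)
  for (k in seq_along(stack$eems))
    X[k, ] <- as.vector(stack$eems[[k]]$intensity)  # column-major = ex-major
  na_count <- colSums(is.na(X))
  keep <- if (missing == "drop") na_count == 0L else na_count < nrow(X)
  if (missing == "impute" && any(na_count > 0L & keep)) {
    for (j in which(na_count > 0L & keep)) {
      nas <- is.na(X[, j])
      X[nas, j] <- mean(X[!nas, j])
    }
  }
  full_map <- data.frame(
    ex = rep(as.numeric(stack$ex_grid), each = d[["em"]]),
    em = rep(as.numeric(stack$em_grid), times = d[["ex"]]))
  X <- X[, keep, drop = FALSE]
  vmap <- data.frame(col = seq_len(sum(keep)), ex = full_map$ex[keep],
                     em = full_map$em[keep])
  rownames(X) <- vapply(stack$eems, function(e)
    paste(e$sample_id, e$replicate_id, sep = "."), character(1))
  list(X = X, vmap = vmap)
}

#' Refold a per-variable vector into an emission x excitation map
#'
#' Inverse of [unfold()] for one row: places `values[i]` at the grid cell
#' recorded in `vmap[i, ]`; cells dropped during unfolding come back as `NA`.
#'
#' @param values numeric vector, `length(values) == nrow(vmap)`.
#' @param vmap variable map from [unfold()].
#' @param ex_grid,em_grid the stack's grids.
#' @return Numeric matrix `[em x ex]` with grid wavelengths as dimnames.
#' @export
fold <- function(values, vmap, ex_grid, em_grid) {
  if (length(values) != nrow(vmap))
    stopf("length(values) = %d but variable map has %d columns",
          length(values), nrow(vmap))
  out <- matrix(NA_real_, length(em_grid), length(ex_grid),
                dimnames = list(as.character(as.numeric(em_grid)),
                                as.character(as.numeric(ex_grid))))
  ri <- match(vmap$em, as.numeric(em_grid))
  ci <- match(vmap$ex, as.numeric(ex_grid))
  out[cbind(ri, ci)] <- values
  out
}

#' Write a stack to disk as manifest + per-scan CSV files
#'
#' Emits `manifest.csv` (`sample_id`, `replicate_id`, `path`), one
#' matrix-dialect EEM CSV per scan, and, when the stack carries reference
#' values, `reference.csv` (`sample_id`, `retinol_iu_dl`).
#'
#' @param stack an `eem_stack`.
#' @param dir destination directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
write_stack_csv <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(stack$eems, function(e) {
    fn <- sprintf("%s_rep%d.csv", e$sample_id, e$replicate_id)
    write_eem_csv(e, file.path(dir, fn))
    data.frame(sample_id = e$sample_id, replicate_id = e$replicate_id, path = fn)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(stack$reference))
    utils::write.csv(data.frame(sample_id = names(stack$reference),
                                retinol_iu_dl = unname(stack$reference)),
                     file.path(dir, "reference.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

#' Read a stack written by [write_stack_csv()]
#'
#' @param dir directory holding `manifest.csv`, the per-scan EEM CSVs and
#'   optionally `reference.csv`.
#' @return An `eem_stack`.
#' @export
read_stack_csv <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stopf("no manifest.csv in %s", dir)
  manifest <- utils::read.csv(mf, colClasses = c(sample_id = "character"))
  eems <- lapply(seq_len(nrow(manifest)), function(i)
    read_eem_csv(file.path(dir, manifest$path[i]),
                 sample_id = manifest$sample_id[i],
                 replicate_id = manifest$replicate_id[i]))
  ref_path <- file.path(dir, "reference.csv")
  reference <- NULL
  if (file.exists(ref_path)) {
    rf <- utils::read.csv(ref_path, colClasses = c(sample_id = "character"))
    reference <- stats::setNames(rf$retinol_iu_dl, rf$sample_id)
  }
  build_stack(eems, reference = reference)
}
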
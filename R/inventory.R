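#' Spectral inventory
#'
#' An inventory bundles a shared wavelength grid, per-sample metadata for a
#' set of tissue-engineered constructs, and the replicate-level
#' diffuse-reflectance NIR spectra. Metadata carries the incubation day
#' (7 or 28), a control flag, and the four binary non-neotissue constituent
#' flags: `mper` (cell-lysis storage buffer), `hav` (N-cadherin mimetic
#' peptide conjugated to the NorHA scaffold), `bmp9` and `tgfb1` (growth
#' factors supplemented to the culture medium; mutually exclusive).
#'
#' @param grid numeric vector of wavelengths in nm, strictly increasing.
#' @param meta data.frame with columns `sample_id`, `day`, `is_control`,
#'   `mper`, `hav`, `bmp9`, `tgfb1`.
#' @param spectra numeric matrix, one row per replicate spectrum, one column
#'   per channel of `grid`. May have zero rows for a metadata-only roster.
#' @param key data.frame with columns `sample_id`, `replicate` identifying
#'   the rows of `spectra`.
#' @return an object of class `nir_inventory`.
#' @export
nir_inventory <- function(grid, meta, spectra = NULL, key = NULL) {
  grid <- as.numeric(grid)
  if (length(grid) < 1 || anyNA(grid) || any(diff(grid) <= 0)) {
    abort("wavelength grid must be strictly increasing and free of NAs")
  }
  required <- c("sample_id", "day", "is_control", CONSTITUENTS)
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    abort("metadata is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  meta <- as.data.frame(meta)[required]
  meta$sample_id <- as.character(meta$sample_id)
  for (fl in c("is_control", CONSTITUENTS)) meta[[fl]] <- as.logical(meta[[fl]])
  if (anyDuplicated(meta$sample_id)) {
    abort("duplicated sample_id: %s",
          paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  bad_day <- !(meta$day %in% c(7L, 28L))
  if (any(bad_day)) {
    abort("incubation day must be 7 or 28; offending sample(s): %s",
          paste(meta$sample_id[bad_day], collapse = ", "))
  }
  both_gf <- meta$bmp9 & meta$tgfb1
  if (any(both_gf)) {
    abort("bmp9 and tgfb1 cannot both be present (media carry one growth factor); offending sample(s): %s",
          paste(meta$sample_id[both_gf], collapse = ", "))
  }
  bad_ctrl <- meta$is_control & (meta$hav | meta$bmp9 | meta$tgfb1)
  if (any(bad_ctrl)) {
    abort("control samples carry no HAV conjugation or growth factors; offending sample(s): %s",
          paste(meta$sample_id[bad_ctrl], collapse = ", "))
  }

  if (is.null(spectra)) {
    spectra <- matrix(numeric(0), nrow = 0, ncol = length(grid))
    key <- data.frame(sample_id = character(0), replicate = integer(0))
  }
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(grid)) {
    abort("spectra have %d channels but the grid has %d", ncol(spectra), length(grid))
  }
  if (nrow(spectra) > 0 && any(!is.finite(spectra))) {
    abort("non-finite intensity values in spectra")
  }
  key <- as.data.frame(key)
  key$sample_id <- as.character(key$sample_id)
  key$replicate <- as.integer(key$replicate)
  if (nrow(key) != nrow(spectra)) abort("spectrum key has %d rows for %d spectra", nrow(key), nrow(spectra))
  if (nrow(key) > 0) {
    if (any(key$replicate < 1L)) abort("replicate indices must be >= 1")
    unknown <- setdiff(key$sample_id, meta$sample_id)
    if (length(unknown) > 0) {
      abort("spectra reference unknown sample_id(s): %s", paste(unknown, collapse = ", "))
    }
    dup <- duplicated(key[c("sample_id", "replicate")])
    if (any(dup)) {
      abort("duplicated (sample_id, replicate) key: (%s, %d)",
            key$sample_id[dup][1], key$replicate[dup][1])
    }
  }
  dimnames(spectra) <- NULL
  row.names(meta) <- NULL
  row.names(key) <- NULL
  structure(list(grid = grid, meta = meta, spectra = spectra, key = key),
            class = "nir_inventory")
}

#' @export
print.nir_inventory <- function(x, ...) {
  cat(sprintf("<nir_inventory> %d samples (%d controls), %d spectra, %d channels (%.1f-%.1f nm)\n",
              nrow(x$meta), sum(x$meta$is_control), nrow(x$spectra),
              length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

n_replicates <- function(inv) {
  tab <- table(factor(inv$key$sample_id, levels = inv$meta$sample_id))
  stats::setNames(as.integer(tab), inv$meta$sample_id)
}

#' Read an inventory from delimited text
#'
#' Reads replicate-level spectra and per-sample metadata from two CSV files.
#' The canonical spectra dialect is long format with columns
#' `sample_id, replicate, wavelength_nm, intensity`; wide format (columns
#' `sample_id, replicate`, then one numeric-named column per wavelength) is
#' also accepted. Metadata columns are `sample_id, day, is_control, mper,
#' hav, bmp9, tgfb1` with flags coded 0/1. Spectra rows whose `sample_id`
#' does not appear in the metadata are dropped with a warning.
#'
#' @param spectra_path,metadata_path paths to the two CSV files.
#' @return a validated [nir_inventory()].
#' @export
read_inventory <- function(spectra_path, metadata_path) {
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  sp <- utils::read.csv(spectra_path, stringsAsFactors = FALSE, check.names = FALSE)

  long <- all(c("sample_id", "replicate", "wavelength_nm", "intensity") %in% names(sp))
  if (!long) {
    if (!all(c("sample_id", "replicate") %in% names(sp))) {
      abort("spectra table %s needs either long columns (sample_id, replicate, wavelength_nm, intensity) or wide columns (sample_id, replicate, <wavelengths>)",
            spectra_path)
    }
    wl_cols <- setdiff(names(sp), c("sample_id", "replicate"))
    wl <- suppressWarnings(as.numeric(wl_cols))
    if (anyNA(wl)) {
      abort("wide spectra table has non-numeric wavelength column(s): %s",
            paste(wl_cols[is.na(wl)], collapse = ", "))
    }
    sp <- data.frame(
      sample_id = rep(as.character(sp$sample_id), times = length(wl_cols)),
      replicate = rep(as.integer(sp$replicate), times = length(wl_cols)),
      wavelength_nm = rep(wl, each = nrow(sp)),
      intensity = unlist(sp[wl_cols], use.names = FALSE)
    )
  }
  if (!is.numeric(sp$intensity)) {
    conv <- suppressWarnings(as.numeric(sp$intensity))
    bad <- !is.na(sp$intensity) & is.na(conv)
    if (any(bad)) {
      abort("non-numeric intensity value '%s' in %s",
            as.character(sp$intensity[bad][1]), spectra_path)
    }
    sp$intensity <- conv
  }
  if (anyNA(sp$intensity)) abort("missing intensity values in %s", spectra_path)

  unknown <- setdiff(unique(sp$sample_id), as.character(meta$sample_id))
  if (length(unknown) > 0) {
    warning(sprintf("dropping spectra for %d unknown sample_id(s): %s",
                    length(unknown), paste(unknown, collapse = ", ")), call. = FALSE)
    sp <- sp[!(sp$sample_id %in% unknown), , drop = FALSE]
  }

  dupk <- duplicated(sp[c("sample_id", "replicate", "wavelength_nm")])
  if (any(dupk)) {
    abort("duplicated (sample_id, replicate, wavelength) key: (%s, %d, %s)",
          sp$sample_id[dupk][1], sp$replicate[dupk][1],
          format(sp$wavelength_nm[dupk][1]))
  }

  grid <- sort(unique(sp$wavelength_nm))
  keys <- unique(sp[c("sample_id", "replicate")])
  keys <- keys[order(keys$sample_id, keys$replicate), , drop = FALSE]
  idx_row <- match(paste(sp$sample_id, sp$replicate), paste(keys$sample_id, keys$replicate))
  idx_col <- match(sp$wavelength_nm, grid)
  X <- matrix(NA_real_, nrow(keys), length(grid))
  X[cbind(idx_row, idx_col)] <- sp$intensity
  if (anyNA(X)) {
    miss <- which(rowSums(is.na(X)) > 0)[1]
    abort("spectrum (%s, %d) does not cover the full wavelength grid",
          keys$sample_id[miss], keys$replicate[miss])
  }
  nir_inventory(grid, meta, X, keys)
}

#' Write an inventory to delimited text
#'
#' Writes the long-format spectra table and the metadata table used by
#' [read_inventory()]. Wavelengths and intensities are written at full
#' double precision so that a read/write/read cycle is lossless; the
#' one-decimal wavelength convention applies to reporting exports only.
#'
#' @param inv an [nir_inventory()].
#' @param spectra_path,metadata_path output CSV paths.
#' @return `inv`, invisibly.
#' @export
write_inventory <- function(inv, spectra_path, metadata_path) {
  meta_out <- inv$meta
  for (fl in c("is_control", CONSTITUENTS)) meta_out[[fl]] <- as.integer(meta_out[[fl]])
  utils::write.csv(meta_out, metadata_path, row.names = FALSE, quote = FALSE)
  n_chan <- length(inv$grid)
  long <- data.frame(
    sample_id = rep(inv$key$sample_id, each = n_chan),
    replicate = rep(inv$key$replicate, each = n_chan),
    wavelength_nm = sprintf("%.17g", rep(inv$grid, times = nrow(inv$spectra))),
    intensity = sprintf("%.17g", as.vector(t(inv$spectra)))
  )
  utils::write.csv(long, spectra_path, row.names = FALSE, quote = FALSE)
  invisible(inv)
}

#' Average technical replicates
#'
#' Collapses each sample's replicate spectra to their channel-wise arithmetic
#' mean, yielding one spectrum per sample (replicate index 1).
#'
#' @param inv an [nir_inventory()] in which every sample has at least one
#'   replicate spectrum.
#' @return an inventory with exactly one spectrum per sample.
#' @export
average_replicates <- function(inv) {
  reps <- n_replicates(inv)
  if (any(reps == 0)) {
    abort("cannot average: sample(s) without replicates: %s",
          paste(names(reps)[reps == 0], collapse = ", "))
  }
  X <- sample_mean_matrix(inv)
  key <- data.frame(sample_id = inv$meta$sample_id, replicate = 1L)
  nir_inventory(inv$grid, inv$meta, X, key)
}

# per-sample mean spectra as a matrix aligned with inv$meta rows
sample_mean_matrix <- function(inv) {
  f <- factor(inv$key$sample_id, levels = inv$meta$sample_id)
  X <- rowsum(inv$spectra, f) / as.vector(table(f))
  dimnames(X) <- NULL
  X
}

#' Drop channels with no variance
#'
#' Removes wavelength channels whose intensity is identical across every
#' spectrum in the inventory (data cleaning applied before the Monte Carlo
#' stage).
#'
#' @param inv an [nir_inventory()] with at least one spectrum.
#' @return a list with elements `inventory` (channels removed) and `kept`
#'   (integer indices of the surviving channels in the original grid).
#' @export
drop_zero_variance_channels <- function(inv) {
  if (nrow(inv$spectra) == 0) abort("inventory has no spectra")
  constant <- apply(inv$spectra, 2, function(col) all(col == col[1]))
  if (all(constant)) abort("degenerate dataset: every channel is constant")
  kept <- which(!constant)
  out <- nir_inventory(inv$grid[kept], inv$meta,
                       inv$spectra[, kept, drop = FALSE], inv$key)
  list(inventory = out, kept = kept)
}

#' Fill in missing technical replicates
#'
#' Brings every sample up to `target_count` replicates by simple replacement:
#' the sample's first available replicate (smallest replicate index) is
#' duplicated as many times as needed. Samples already complete are left
#' untouched.
#'
#' @param inv an [nir_inventory()] where every sample has >= 1 replicate.
#' @param target_count replicates per sample after imputation (default 3).
#' @return the completed inventory.
#' @export
impute_missing_replicates <- function(inv, target_count = 3L) {
  reps <- n_replicates(inv)
  if (any(reps == 0)) {
    abort("sample(s) without any replicate cannot be imputed: %s",
          paste(names(reps)[reps == 0], collapse = ", "))
  }
  short <- names(reps)[reps < target_count]
  if (length(short) == 0) return(inv)
  X <- inv$spectra
  key <- inv$key
  for (sid in short) {
    rows <- which(key$sample_id == sid)
    first <- rows[which.min(key$replicate[rows])]
    n_add <- target_count - length(rows)
    X <- rbind(X, X[rep(first, n_add), , drop = FALSE])
    key <- rbind(key, data.frame(sample_id = sid,
                                 replicate = max(key$replicate[rows]) + seq_len(n_add)))
  }
  ord <- order(key$sample_id, key$replicate)
  nir_inventory(inv$grid, inv$meta, X[ord, , drop = FALSE], key[ord, , drop = FALSE])
}

# restrict an inventory to a subset of sample ids (keeps meta order)
subset_inventory <- function(inv, ids) {
  keep_meta <- inv$meta$sample_id %in% ids
  keep_spec <- inv$key$sample_id %in% ids
  nir_inventory(inv$grid, inv$meta[keep_meta, , drop = FALSE],
                inv$spectra[keep_spec, , drop = FALSE],
                inv$key[keep_spec, , drop = FALSE])
}
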
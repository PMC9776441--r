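# Dataset construction: complete + multi-view partial cloud pairs written to
# PLY, with a stratified train/val/test split recorded in a plain-text
# manifest.

#' Stratified split sizes for one category
#'
#' Validation and test sizes are `floor(ratio * n)`; the remainder goes to
#' train. On 1694 vessels and 215 aneurysms at 8:1:1 this yields
#' 1356:169:169 and 173:21:21.
#'
#' @param n number of samples in the category.
#' @param split_ratio length-3 numeric summing to 1 (train, val, test).
#' @return named integer vector `c(train, val, test)`.
#' @export
split_counts <- function(n, split_ratio = c(0.8, 0.1, 0.1)) {
  stopifnot(length(split_ratio) == 3L, abs(sum(split_ratio) - 1) < 1e-9)
  n_val <- floor(split_ratio[2] * n)
  n_test <- floor(split_ratio[3] * n)
  c(train = n - n_val - n_test, val = n_val, test = n_test)
}

#' Assign stratified splits to categorized records
#'
#' Shuffles within each category and allocates splits per [split_counts()].
#' A category with fewer than 3 records is placed wholly in train with a
#' warning.
#'
#' @param categories character vector, one label per record.
#' @param split_ratio length-3 numeric summing to 1.
#' @param rng_seed integer seed for the within-category shuffle.
#' @return character vector of `"train"`, `"val"`, `"test"`.
#' @export
assign_splits <- function(categories, split_ratio = c(0.8, 0.1, 0.1), rng_seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(rng_seed))
  out <- character(length(categories))
  for (cat in unique(categories)) {
    idx <- which(categories == cat)
    if (length(idx) < 3L) {
      warning("category '", cat, "' has fewer records than split bins; ",
              "placing all in train", call. = FALSE)
      out[idx] <- "train"
      next
    }
    cnt <- split_counts(length(idx), split_ratio)
    lab <- rep(c("train", "val", "test"), times = cnt)
    out[idx] <- lab[order(sample.int(length(idx)))]
  }
  out
}

.derive_seed <- function(base, i, j = 0L) {
  as.integer((as.numeric(base) + 10007 * i + 101 * j) %% 2147483647)
}

#' Build a completion dataset from meshes
#'
#' For each mesh: samples an area-uniform complete cloud, normalizes it to
#' the unit sphere, applies the same transform to the mesh, renders
#' `n_views` partial clouds from random viewpoints, and writes everything to
#' PLY under `out_dir`. The manifest records categories, paths, splits and
#' seeds for full reproducibility.
#'
#' @param meshes list of `surface_mesh`.
#' @param categories character vector of per-mesh labels (e.g. `"vessel"`,
#'   `"aneurysm"`).
#' @param out_dir output directory (created if missing).
#' @param n_complete points per complete cloud (default 2048).
#' @param n_partial points per partial cloud (default 512).
#' @param n_views partial views per mesh (default 8).
#' @param split_ratio train/val/test proportions (default 8:1:1).
#' @param rng_seed integer master seed; per-(sample, view) seeds are derived
#'   from it.
#' @param resolution,distance depth-rendering parameters, see [view_spec()].
#' @return a `dataset_manifest` data.frame (invisibly written to
#'   `manifest.tsv` in `out_dir`).
#' @export
build_dataset <- function(meshes, categories, out_dir,
                          n_complete = 2048L, n_partial = 512L, n_views = 8L,
                          split_ratio = c(0.8, 0.1, 0.1), rng_seed = 1L,
                          resolution = 160L, distance = 2.5) {
  stopifnot(length(meshes) == length(categories), n_views >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  splits <- assign_splits(categories, split_ratio, rng_seed)
  rows <- vector("list", length(meshes))
  for (i in seq_along(meshes)) {
    sid <- sprintf("sample_%04d", i)
    comp_seed <- .derive_seed(rng_seed, i)
    complete <- sample_complete(meshes[[i]], n_complete, comp_seed)
    tr <- normalize_cloud(complete)
    mesh_n <- normalize_mesh(meshes[[i]], tr)
    comp_path <- file.path(out_dir, paste0(sid, "_complete.ply"))
    write_ply_cloud(tr$points, comp_path)
    views <- random_views(n_views, .derive_seed(rng_seed, i, 1L),
                          resolution = resolution, distance = distance)
    ppaths <- character(n_views)
    for (j in seq_len(n_views)) {
      part <- render_partial(mesh_n, views[[j]], n_partial,
                             .derive_seed(rng_seed, i, j + 1L))
      ppaths[j] <- file.path(out_dir, sprintf("%s_partial_%02d.ply", sid, j))
      write_ply_cloud(part, ppaths[j])
    }
    rows[[i]] <- data.frame(sample_id = sid, category = categories[i],
                            split = splits[i], complete_path = comp_path,
                            partial_paths = paste(ppaths, collapse = ";"),
                            rng_seed = comp_seed, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  attr(manifest, "params") <- list(n_complete = n_complete, n_partial = n_partial,
                                   n_views = n_views, split_ratio = split_ratio,
                                   rng_seed = rng_seed)
  class(manifest) <- c("dataset_manifest", "data.frame")
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}

#' Write / read a dataset manifest
#'
#' Line-delimited TSV with `#key<TAB>value` header lines recording the
#' generation parameters and master seed.
#'
#' @param manifest a `dataset_manifest`.
#' @param path file path.
#' @export
write_manifest <- function(manifest, path) {
  p <- attr(manifest, "params")
  hdr <- sprintf("#%s\t%s", names(p),
                 vapply(p, function(x) paste(x, collapse = ","), character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(manifest, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @return `read_manifest`: a `dataset_manifest` data.frame.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  params <- list()
  for (ln in hdr) {
    kv <- strsplit(sub("^#", "", ln), "\t")[[1]]
    vals <- strsplit(kv[2], ",")[[1]]
    num <- suppressWarnings(as.numeric(vals))
    params[[kv[1]]] <- if (anyNA(num)) vals else num
  }
  body <- lines[!startsWith(lines, "#")]
  manifest <- utils::read.table(text = body, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  attr(manifest, "params") <- params
  class(manifest) <- c("dataset_manifest", "data.frame")
  manifest
}

manifest_partials <- function(manifest, i) {
  strsplit(manifest$partial_paths[i], ";", fixed = TRUE)[[1]]
}
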
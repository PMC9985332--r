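#' Load a single-cell expression matrix
#'
#' Reads a cells x genes expression matrix, cluster labels and an optional
#' 2-D embedding from one of three on-disk formats:
#'
#' * `"h5ad"`: an AnnData container. `X` may be dense or CSR/CSC sparse;
#'   cluster labels are read from `obs/<cluster_key>` (plain or categorical
#'   encoding) and the embedding from `obsm/<embedding_key>`. Requires the
#'   `rhdf5` package.
#' * `"tsv"`: tab-separated values, header row of gene names, first column of
#'   cell ids. Cluster labels, when present, come from a sidecar file
#'   `<path>.clusters.tsv` with columns `cell_id` and `cluster`.
#' * `"mtx"`: MatrixMarket coordinate file (genes may be on either axis; the
#'   axis matching the index files decides) with sidecar index files
#'   `<path>.cells.txt` and `<path>.genes.txt`, one id per line, plus the
#'   optional `<path>.clusters.tsv` sidecar.
#'
#' @param path path to the matrix file.
#' @param format one of `"h5ad"`, `"tsv"`, `"mtx"`.
#' @param cluster_key for h5ad, the `obs` column holding cluster labels.
#' @param embedding_key for h5ad, the `obsm` key holding 2-D coordinates
#'   (e.g. `"X_umap"`), or `NULL` to skip.
#' @param log_transformed whether the stored values are already
#'   log2(x+1)-transformed.
#' @return an [ExpressionMatrix][expression_matrix]; cell and gene order are
#'   preserved from the file.
#' @export
load_expression <- function(path, format = c("h5ad", "tsv", "mtx"),
                            cluster_key = "cluster", embedding_key = NULL,
                            log_transformed = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    h5ad = read_h5ad(path, cluster_key, embedding_key, log_transformed),
    tsv = read_tsv_matrix(path, log_transformed),
    mtx = read_mtx_matrix(path, log_transformed)
  )
}

read_tsv_matrix <- function(path, log_transformed = FALSE) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  cell_ids <- as.character(dt[[1]])
  vals <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values in ", path)
  rownames(vals) <- cell_ids
  labs <- read_cluster_sidecar(path, cell_ids)
  expression_matrix(vals, cell_ids = cell_ids, gene_names = colnames(vals),
                    cluster_labels = labs, log_transformed = log_transformed)
}

read_mtx_matrix <- function(path, log_transformed = FALSE) {
  m <- Matrix::readMM(path)
  cells <- readLines(paste0(path, ".cells.txt"))
  genes <- readLines(paste0(path, ".genes.txt"))
  if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
    m <- Matrix::t(m)                       # stored genes x cells
  } else if (!(nrow(m) == length(cells) && ncol(m) == length(genes))) {
    stop("matrix dimensions do not match the .cells/.genes index files")
  }
  m <- methods::as(m, "CsparseMatrix")
  labs <- read_cluster_sidecar(path, cells)
  expression_matrix(m, cell_ids = cells, gene_names = genes,
                    cluster_labels = labs, log_transformed = log_transformed)
}

read_cluster_sidecar <- function(path, cell_ids) {
  sc <- paste0(path, ".clusters.tsv")
  if (!file.exists(sc)) return(NULL)
  dt <- data.table::fread(sc, sep = "\t", header = TRUE, data.table = FALSE)
  labs <- as.character(dt$cluster)[match(cell_ids, as.character(dt$cell_id))]
  if (anyNA(labs)) stop("cluster sidecar ", sc, " is missing some cells")
  labs
}

need_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("reading/writing h5ad requires the 'rhdf5' package; ",
         "use the tsv or mtx format instead")
}

read_h5ad <- function(path, cluster_key, embedding_key, log_transformed) {
  need_rhdf5()
  contents <- rhdf5::h5ls(path)
  x_is_group <- any(contents$group == "/" & contents$name == "X" &
                      contents$otype == "H5I_GROUP")
  if (x_is_group) {
    enc <- rhdf5::h5readAttributes(path, "X")[["encoding-type"]]
    dat <- rhdf5::h5read(path, "X/data")
    idx <- as.integer(rhdf5::h5read(path, "X/indices"))
    ptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    shp <- as.integer(rhdf5::h5readAttributes(path, "X")[["shape"]])
    if (identical(enc, "csr_matrix")) {
      # row-compressed over obs: equals a column-compressed genes x obs matrix
      vals <- Matrix::t(Matrix::sparseMatrix(i = idx + 1L, p = ptr, x = as.numeric(dat),
                                             dims = c(shp[2], shp[1])))
    } else if (identical(enc, "csc_matrix")) {
      vals <- Matrix::sparseMatrix(i = idx + 1L, p = ptr, x = as.numeric(dat),
                                   dims = c(shp[1], shp[2]))
    } else stop("unsupported X encoding in ", path, ": ", enc)
    vals <- methods::as(vals, "CsparseMatrix")
  } else {
    vals <- rhdf5::h5read(path, "X")
    if (!is.numeric(vals)) stop("non-numeric X matrix in ", path)
    vals <- t(vals)                         # HDF5 dims are reversed in R
  }
  obs <- read_h5ad_frame(path, "obs")
  var <- read_h5ad_frame(path, "var")
  if (!cluster_key %in% names(obs$columns))
    stop("cluster key '", cluster_key, "' not found in obs; available keys: ",
         paste(names(obs$columns), collapse = ", "))
  emb <- NULL
  if (!is.null(embedding_key)) {
    obsm <- tryCatch(rhdf5::h5read(path, paste0("obsm/", embedding_key)),
                     error = function(e) NULL)
    if (is.null(obsm))
      stop("embedding key '", embedding_key, "' not found in obsm")
    emb <- t(obsm)[, 1:2, drop = FALSE]
  }
  expression_matrix(vals, cell_ids = obs$index, gene_names = var$index,
                    cluster_labels = obs$columns[[cluster_key]],
                    embedding = emb, log_transformed = log_transformed)
}

# obs/var dataframe groups: _index attribute names the index dataset;
# categorical columns are groups holding categories + codes
read_h5ad_frame <- function(path, group) {
  at <- rhdf5::h5readAttributes(path, group)
  idx_name <- if (!is.null(at[["_index"]])) at[["_index"]] else "_index"
  index <- as.character(rhdf5::h5read(path, paste0(group, "/", idx_name)))
  contents <- rhdf5::h5ls(path)
  here <- contents[contents$group == paste0("/", group), , drop = FALSE]
  cols <- list()
  for (i in seq_len(nrow(here))) {
    nm <- here$name[i]
    if (nm == idx_name) next
    full <- paste0(group, "/", nm)
    if (here$otype[i] == "H5I_GROUP") {
      sub <- rhdf5::h5ls(path)
      kids <- sub$name[sub$group == paste0("/", full)]
      if (all(c("categories", "codes") %in% kids)) {
        cats <- as.character(rhdf5::h5read(path, paste0(full, "/categories")))
        codes <- as.integer(rhdf5::h5read(path, paste0(full, "/codes")))
        v <- rep(NA_character_, length(codes))
        v[codes >= 0] <- cats[codes[codes >= 0] + 1L]
        cols[[nm]] <- v
      }
    } else {
      cols[[nm]] <- as.vector(rhdf5::h5read(path, full))
    }
  }
  list(index = index, columns = cols)
}

#' Write an ExpressionMatrix to disk
#'
#' Inverse of [load_expression()] for the same three formats. The h5ad writer
#' produces a minimal AnnData-compatible container (dense `X`, string-encoded
#' `obs`/`var`, optional `obsm` embedding).
#'
#' @param em an [ExpressionMatrix][expression_matrix].
#' @param path output path.
#' @param format one of `"tsv"`, `"mtx"`, `"h5ad"`.
#' @param cluster_key obs column name used for the cluster labels (h5ad), or
#'   the column name of the cluster sidecar file (tsv/mtx).
#' @param embedding_key obsm key used for the embedding (h5ad only).
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, format = c("tsv", "mtx", "h5ad"),
                             cluster_key = "cluster", embedding_key = "X_umap") {
  format <- match.arg(format)
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (format == "tsv") {
    dt <- data.table::data.table(cell_id = em$cell_ids)
    dt <- cbind(dt, data.table::as.data.table(as.matrix(em$values)))
    data.table::setnames(dt, c("cell_id", em$gene_names))
    data.table::fwrite(dt, path, sep = "\t")
    write_cluster_sidecar(em, path)
  } else if (format == "mtx") {
    Matrix::writeMM(methods::as(methods::as(em$values, "CsparseMatrix"), "generalMatrix"), path)
    writeLines(em$cell_ids, paste0(path, ".cells.txt"))
    writeLines(em$gene_names, paste0(path, ".genes.txt"))
    write_cluster_sidecar(em, path)
  } else {
    write_h5ad(em, path, cluster_key, embedding_key)
  }
  invisible(path)
}

write_cluster_sidecar <- function(em, path) {
  if (is.null(em$cluster_labels)) return(invisible(NULL))
  data.table::fwrite(
    data.table::data.table(cell_id = em$cell_ids, cluster = em$cluster_labels),
    paste0(path, ".clusters.tsv"), sep = "\t")
}

write_h5ad <- function(em, path, cluster_key, embedding_key) {
  need_rhdf5()
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  h5 <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(h5), add = TRUE)
  # R writes column-major with reversed dims: genes x cells here comes out as
  # an obs x var C-order dataset, which is what AnnData expects
  rhdf5::h5write(t(as.matrix(em$values)), h5, "X")
  write_h5ad_frame(h5, "obs", em$cell_ids,
                   cols = if (!is.null(em$cluster_labels))
                     stats::setNames(list(em$cluster_labels), cluster_key))
  write_h5ad_frame(h5, "var", em$gene_names, cols = NULL)
  if (!is.null(em$embedding)) {
    rhdf5::h5createGroup(h5, "obsm")
    rhdf5::h5write(t(em$embedding), h5, paste0("obsm/", embedding_key))
  }
  h5ad_attr(h5, "X", "encoding-type", "array")
  h5ad_attr(h5, "X", "encoding-version", "0.2.0")
  h5ad_attr(h5, ".", "encoding-type", "anndata")
  h5ad_attr(h5, ".", "encoding-version", "0.1.0")
  invisible(path)
}

write_h5ad_frame <- function(h5, group, index, cols) {
  rhdf5::h5createGroup(h5, group)
  rhdf5::h5write(index, h5, paste0(group, "/_index"))
  for (nm in names(cols))
    rhdf5::h5write(as.character(cols[[nm]]), h5, paste0(group, "/", nm))
  h5ad_attr(h5, group, "encoding-type", "dataframe")
  h5ad_attr(h5, group, "encoding-version", "0.2.0")
  h5ad_attr(h5, group, "_index", "_index")
  h5ad_attr(h5, group, "column-order", as.character(names(cols)),
            scalar = FALSE)
  h5ad_attr(h5, paste0(group, "/_index"), "encoding-type", "string-array")
  h5ad_attr(h5, paste0(group, "/_index"), "encoding-version", "0.2.0")
  for (nm in names(cols)) {
    h5ad_attr(h5, paste0(group, "/", nm), "encoding-type", "string-array")
    h5ad_attr(h5, paste0(group, "/", nm), "encoding-version", "0.2.0")
  }
}

h5ad_attr <- function(h5, obj, name, value, scalar = length(value) == 1L) {
  loc <- if (identical(obj, ".")) rhdf5::H5Gopen(h5, "/") else {
    info <- rhdf5::h5ls(h5)
    full <- paste0(ifelse(info$group == "/", "", info$group), "/", info$name)
    if (any(full == paste0("/", obj) & info$otype == "H5I_GROUP"))
      rhdf5::H5Gopen(h5, obj) else rhdf5::H5Dopen(h5, obj)
  }
  on.exit({
    if (inherits(loc, "H5IdComponent")) {
      if (rhdf5::H5Iget_type(loc) == "H5I_GROUP") rhdf5::H5Gclose(loc)
      else rhdf5::H5Dclose(loc)
    }
  }, add = TRUE)
  if (length(value) == 0L) {
    # rhdf5's high-level writer cannot emit a zero-length attribute, but the
    # AnnData schema requires e.g. an empty column-order array
    sid <- rhdf5::H5Screate_simple(0)
    tid <- rhdf5::H5Tcopy("H5T_C_S1")
    rhdf5::H5Tset_size(tid, 8L)      # dtype is irrelevant for a 0-length array
    rhdf5::H5Tset_cset(tid, "UTF-8")
    aid <- rhdf5::H5Acreate(loc, name, tid, sid)
    rhdf5::H5Aclose(aid)
    rhdf5::H5Sclose(sid)
  } else {
    rhdf5::h5writeAttribute(value, loc, name,
                            variableLengthString = TRUE, asScalar = scalar)
  }
}

#' Read a transcription-factor list
#'
#' Plain text, one gene symbol per line; blank lines and `#` comments are
#' ignored.
#'
#' @param path path to the TF list file.
#' @return character vector of unique TF symbols.
#' @export
read_tf_list <- function(path) {
  if (!file.exists(path)) stop("TF list not found: ", path)
  x <- readLines(path)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (length(x) == 0L) stop("TF list is empty: ", path)
  unique(x)
}

#' Keep the TFs that are usable in a matrix
#'
#' TF names absent from the gene axis are dropped with a warning; the
#' remainder are the usable regressors.
#' @param tfs character vector of TF symbols.
#' @param em an [ExpressionMatrix][expression_matrix].
#' @return character vector of TFs present in `em`.
#' @export
match_tfs <- function(tfs, em) {
  keep <- tfs %in% em$gene_names
  if (!all(keep))
    warning(sum(!keep), " TF name(s) not present in the matrix were ignored: ",
            paste(utils::head(tfs[!keep], 5), collapse = ", "))
  if (!any(keep)) stop("none of the TF names are present in the matrix")
  tfs[keep]
}
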
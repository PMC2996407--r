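TABLE_SCHEMA <- "motifhash-table-1"

#' Build a persistent label table from targets
#'
#' Preprocesses a set of targets into an on-disk table keyed by sorted
#' residue-label tuples.  The table is a documented hierarchical directory
#' store (`meta.json` header; one group of datasets per target holding the
#' residue table, label counts and neighbor lists; one gzip-compressed
#' matrix dataset per label key holding all reference sets with those
#' labels, with the `target_id` column acting as the row-block index that
#' maps row blocks to targets).  Lookups read only the requested key's
#' dataset, so matching touches a small fraction of the file set.
#' Preprocessing is performed once; any motif can then be matched against
#' the same table.
#'
#' @param targets list of `target_structure` objects (depths computed when
#'   `params$check_depth` is `TRUE`).
#' @param params [geometric_params()] used to enumerate reference sets;
#'   stored in the table header and checked again at match time.
#' @param path directory to create (must not contain a table already unless
#'   `overwrite = TRUE`).
#' @param r neighbor-list query radius, Angstrom (lists stored at `2r`;
#'   default 7, the match rejection threshold).
#' @param overwrite replace an existing table at `path`.
#' @param on_error `"skip"` (default: log and skip a failing target) or
#'   `"stop"`.
#' @return a `label_table` handle (also obtainable later via
#'   [open_table()]).
#' @export
build_table <- function(targets, params = geometric_params(), path,
                        r = 7, overwrite = FALSE, on_error = c("skip", "stop")) {
  on_error <- match.arg(on_error)
  ids <- vapply(targets, function(t) t$target_id, "")
  if (anyDuplicated(ids))
    stop("duplicate target_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- grep("[^A-Za-z0-9._-]", ids)
  if (length(bad))
    stop("target_id(s) contain characters unsafe for storage: ",
         paste(ids[bad], collapse = ", "))
  if (dir.exists(path)) {
    if (!overwrite && file.exists(file.path(path, "meta.json")))
      stop("a table already exists at '", path, "' (use overwrite = TRUE)")
    unlink(path, recursive = TRUE)
  }
  dir.create(path, recursive = TRUE)
  dir.create(file.path(path, "targets"))
  dir.create(file.path(path, "keys"))

  key_rows <- new.env(parent = emptyenv(), hash = TRUE)
  stored <- character()
  skipped <- character()
  for (tg in targets) {
    res <- tryCatch({
      rs <- enumerate_reference_sets(tg, params)
      nb <- precompute_neighbor_lists(tg, r = r)
      write_target_group(path, tg, nb)
      if (nrow(rs$indices)) {
        by_key <- split(seq_len(nrow(rs$indices)), rs$key)
        for (k in names(by_key)) {
          rows <- rs$indices[by_key[[k]], , drop = FALSE]
          block <- cbind(data.frame(target_id = tg$target_id,
                                    stringsAsFactors = FALSE),
                         as.data.frame(rows))
          key_rows[[k]] <- c(key_rows[[k]], list(block))
        }
      }
      TRUE
    }, error = function(e) e)
    if (isTRUE(res)) {
      stored <- c(stored, tg$target_id)
    } else {
      if (on_error == "stop") stop(res)
      skipped <- c(skipped, tg$target_id)
      warning("skipping target '", tg$target_id, "': ",
              conditionMessage(res))
    }
  }
  n <- params$n
  for (k in sort(ls(key_rows))) {
    blocks <- do.call(rbind, key_rows[[k]])
    names(blocks) <- c("target_id", paste0("i", seq_len(n)))
    con <- gzfile(file.path(path, "keys", paste0(k, ".tsv.gz")), "w")
    write.table(blocks, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  meta <- list(schema = TABLE_SCHEMA,
               codec = "gzip",
               neighbor_radius_2r = 2 * r,
               params = unclass(params),
               targets = as.list(sort(stored)),
               skipped = as.list(skipped))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  open_table(path)
}

write_target_group <- function(path, tg, nb) {
  base <- file.path(path, "targets", tg$target_id)
  res <- tg$residues
  df <- data.frame(chain_id = res$chain_id,
                   seq_number = res$seq_number,
                   insertion_code = res$insertion_code,
                   label = res$label,
                   ca_x = tg$ca[, 1L], ca_y = tg$ca[, 2L], ca_z = tg$ca[, 3L],
                   cen_x = tg$centroid[, 1L], cen_y = tg$centroid[, 2L],
                   cen_z = tg$centroid[, 3L],
                   cen_fallback = as.integer(tg$centroid_flag),
                   depth = tg$depth,
                   stringsAsFactors = FALSE)
  con <- gzfile(paste0(base, ".residues.tsv.gz"), "w")
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  cnt <- data.frame(label = names(tg$label_counts),
                    count = as.integer(tg$label_counts),
                    stringsAsFactors = FALSE)
  write.table(cnt, paste0(base, ".counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ii <- rep.int(seq_along(nb$idx), lengths(nb$idx))
  nbr <- data.frame(i = ii,
                    j = unlist(nb$idx, use.names = FALSE),
                    dist = unlist(nb$dist, use.names = FALSE))
  if (!nrow(nbr)) nbr <- data.frame(i = integer(), j = integer(),
                                    dist = numeric())
  con <- gzfile(paste0(base, ".neighbors.tsv.gz"), "w")
  write.table(nbr, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
}

#' Open an existing label table
#'
#' @param path table directory created by [build_table()].
#' @return a `label_table` handle: `path`, `params`
#'   ([geometric_params()] used at build time), `targets` (stored ids) and
#'   the raw metadata header.
#' @export
open_table <- function(path) {
  mp <- file.path(path, "meta.json")
  if (!file.exists(mp)) stop("no label table at '", path, "'")
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  if (!identical(meta$schema, TABLE_SCHEMA))
    stop("unsupported table schema '", meta$schema, "' (expected '",
         TABLE_SCHEMA, "')")
  params <- do.call(geometric_params, meta$params)
  structure(list(path = path, params = params,
                 targets = sort(unlist(meta$targets, use.names = FALSE)),
                 meta = meta),
            class = "label_table")
}

#' Look up reference sets under one label key
#'
#' Constant-time (per key) retrieval of all stored reference sets whose
#' sorted label tuple equals `key`, grouped by target.  Only the requested
#' key's dataset is read.
#'
#' @param table a `label_table` handle.
#' @param key sorted character vector of labels (or the concatenated key
#'   string, e.g. `"DHK"`); an unsorted key is an error so that call sites
#'   canonicalize via [label_key()].
#' @param target_filter optional character vector of target ids to restrict
#'   the result to.
#' @return named list mapping `target_id` to an integer matrix of residue
#'   index tuples (one row per stored reference set).
#' @export
lookup <- function(table, key, target_filter = NULL) {
  k <- canonical_key_string(key, table$params$n)
  f <- file.path(table$path, "keys", paste0(k, ".tsv.gz"))
  if (!file.exists(f)) return(setNames(list(), character()))
  tab <- read.delim(gzfile(f), stringsAsFactors = FALSE)
  if (!is.null(target_filter))
    tab <- tab[tab$target_id %in% target_filter, , drop = FALSE]
  if (!nrow(tab)) return(setNames(list(), character()))
  idx <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(idx) <- "integer"
  dimnames(idx) <- NULL
  split_rows(idx, tab$target_id)
}

canonical_key_string <- function(key, n) {
  if (length(key) == 1L && nchar(key) > 1L)
    key <- strsplit(key, "", fixed = TRUE)[[1L]]
  if (length(key) != n)
    stop("key arity ", length(key), " != table tuple size ", n)
  if (is.unsorted(key, strictly = FALSE) ||
      !identical(key, sort(key, method = "radix")))
    stop("label key must be sorted (got ", paste(key, collapse = ""),
         "); canonicalize with label_key()")
  bad <- setdiff(key, AA1)
  if (length(bad))
    stop("not standard amino-acid labels: ", paste(bad, collapse = ", "))
  paste(key, collapse = "")
}

split_rows <- function(idx, ids) {
  groups <- split(seq_along(ids), ids)
  lapply(groups, function(rows) idx[rows, , drop = FALSE])
}

#' Total number of stored reference sets under a key
#'
#' @inheritParams lookup
#' @return integer count (0 for absent keys).
#' @export
key_frequency <- function(table, key, target_filter = NULL) {
  hits <- lookup(table, key, target_filter)
  sum(vapply(hits, nrow, integer(1L)))
}

#' Read a stored target back from the table
#'
#' Round-trips the stored structural data exactly: residue identities,
#' labels, C-alpha coordinates, side-chain centroids, depths, label counts,
#' and the precomputed neighbor lists (attached as attribute
#' `neighbor_lists`).  The atom table is not stored (it is only needed at
#' preprocessing time).
#'
#' @param table a `label_table` handle.
#' @param target_id stored target identifier.
#' @return a `target_structure` with attribute `neighbor_lists`.
#' @export
read_target <- function(table, target_id) {
  base <- file.path(table$path, "targets", target_id)
  f <- paste0(base, ".residues.tsv.gz")
  if (!file.exists(f)) {
    near <- agrep(target_id, table$targets, max.distance = 2, value = TRUE)
    stop("unknown target_id '", target_id, "'",
         if (length(near)) paste0("; near misses: ",
                                  paste(head(near, 5L), collapse = ", "))
         else "")
  }
  df <- read.delim(gzfile(f), stringsAsFactors = FALSE,
                   colClasses = c(chain_id = "character",
                                  insertion_code = "character",
                                  label = "character"))
  df$chain_id[is.na(df$chain_id)] <- ""
  df$insertion_code[is.na(df$insertion_code)] <- ""
  residues <- df[, c("chain_id", "seq_number", "insertion_code", "label")]
  tg <- new_target_structure(
    target_id, residues,
    ca = as.matrix(df[, c("ca_x", "ca_y", "ca_z")]),
    centroid = as.matrix(df[, c("cen_x", "cen_y", "cen_z")]),
    centroid_flag = df$cen_fallback > 0L,
    atoms = NULL,
    depth = df$depth)
  dimnames(tg$ca) <- NULL
  dimnames(tg$centroid) <- NULL
  nbr <- read.delim(gzfile(paste0(base, ".neighbors.tsv.gz")),
                    stringsAsFactors = FALSE)
  N <- nrow(residues)
  idx <- rep(list(integer()), N)
  dst <- rep(list(numeric()), N)
  if (nrow(nbr)) {
    by_i <- split(seq_len(nrow(nbr)), nbr$i)
    for (nm in names(by_i)) {
      i <- as.integer(nm)
      rows <- by_i[[nm]]
      idx[[i]] <- as.integer(nbr$j[rows])
      dst[[i]] <- as.numeric(nbr$dist[rows])
    }
  }
  r2 <- table$meta$neighbor_radius_2r
  nb <- structure(list(radius_2r = r2, idx = idx, dist = dst,
                       grid = build_point_grid(tg$ca, cell = r2)),
                  class = "neighbor_lists")
  attr(tg, "neighbor_lists") <- nb
  tg
}

#' List the target ids stored in a table
#' @param table a `label_table` handle.
#' @return sorted character vector.
#' @export
table_targets <- function(table) table$targets

#' @export
print.label_table <- function(x, ...) {
  nk <- length(list.files(file.path(x$path, "keys")))
  cat("Label table at '", x$path, "': ", length(x$targets),
      " target(s), ", nk, " label key(s)\n", sep = "")
  print(x$params)
  invisible(x)
}
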
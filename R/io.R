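# Readers and writers for the tabular interchange formats, plus the
# config-driven adjustment pipeline with a reproducibility manifest.
# Canonical dialect: TSV with header, UTF-8; comma-separated files are
# accepted on read by sniffing the header line; "." and "" read as missing.

.read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (!grepl("\t", header) && grepl(",", header)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    na.strings = c("NA", ".", ""), stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

.require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("file '", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "))
}

# data line number of row i (header = line 1)
.lineno <- function(i) i + 1L

#' Read a gene-level copy-number table
#'
#' Expects columns \code{sample_id}, \code{gene}, \code{cnr} (observed log2
#' copy-number ratio). Rows with missing ids or a non-finite CNR are rejected
#' with their line numbers.
#'
#' @param path TSV (or CSV) file with a header.
#' @return data.frame of validated rows; a warning lists rejected lines.
#' @export
read_copy_number_table <- function(path) {
  df <- .read_table(path)
  .require_columns(df, c("sample_id", "gene", "cnr"), path)
  if (nrow(df) == 0) {
    warning("empty copy-number table: ", path)
    return(df)
  }
  cnr <- suppressWarnings(as.numeric(df$cnr))
  bad <- !is.finite(cnr) | is.na(df$sample_id) | is.na(df$gene)
  if (any(bad))
    stop("malformed copy-number row(s) at line(s) ",
         paste(.lineno(which(bad)), collapse = ", "), " in ", path)
  df$cnr <- cnr
  df
}

#' Parse an HGVS-like coding-change string
#'
#' Tolerantly parses strings such as \code{"c.506T>C"} (the \code{"c."}
#' prefix optional, case-insensitive) into position, reference and alternate
#' base. Unparsable strings yield missing fields.
#'
#' @param cds_change character vector.
#' @return data.frame with \code{cds_position}, \code{ref_base},
#'   \code{alt_base} (NA where unparsable).
#' @export
parse_cds_change <- function(cds_change) {
  m <- regmatches(cds_change,
                  regexec("^\\s*(?:c\\.)?(\\d+)\\s*([ACGTacgt])\\s*>\\s*([ACGTacgt])\\s*$",
                          cds_change))
  pos <- vapply(m, function(x) if (length(x) == 4)
    as.integer(x[2]) else NA_integer_, integer(1))
  ref <- vapply(m, function(x) if (length(x) == 4)
    toupper(x[3]) else NA_character_, character(1))
  alt <- vapply(m, function(x) if (length(x) == 4)
    toupper(x[4]) else NA_character_, character(1))
  data.frame(cds_position = pos, ref_base = ref, alt_base = alt,
             stringsAsFactors = FALSE)
}

#' Read a variant table
#'
#' Expects columns \code{sample_id}, \code{gene}, \code{vaf}; optional
#' \code{cds_change} (HGVS-like, parsed via [parse_cds_change()]),
#' \code{in_cosmic} and \code{vep_impact}. Rows with VAF outside \[0, 1\] are
#' rejected with line numbers; unparsable \code{cds_change} strings leave the
#' coding fields missing with a warning.
#'
#' @param path TSV (or CSV) file with a header.
#' @return data.frame of validated rows (with parsed \code{cds_position},
#'   \code{ref_base}, \code{alt_base} when \code{cds_change} is present).
#' @export
read_variant_table <- function(path) {
  df <- .read_table(path)
  .require_columns(df, c("sample_id", "gene", "vaf"), path)
  if (nrow(df) == 0) {
    warning("empty variant table: ", path)
    return(df)
  }
  vaf <- suppressWarnings(as.numeric(df$vaf))
  bad <- is.na(vaf) | vaf < 0 | vaf > 1
  if (any(bad)) {
    warning("rejected variant row(s) with VAF outside [0, 1] at line(s) ",
            paste(.lineno(which(bad)), collapse = ", "), " in ", path)
    df <- df[!bad, , drop = FALSE]
    vaf <- vaf[!bad]
  }
  df$vaf <- vaf
  if ("cds_change" %in% names(df)) {
    parsed <- parse_cds_change(df$cds_change)
    unparsable <- !is.na(df$cds_change) & is.na(parsed$cds_position)
    if (any(unparsable))
      warning(sum(unparsable), " cds_change value(s) not parsable; ",
              "coding fields left missing")
    df <- cbind(df, parsed)
  }
  if ("in_cosmic" %in% names(df)) df$in_cosmic <- .parse_bool(df$in_cosmic)
  rownames(df) <- NULL
  df
}

#' Read a purity/ploidy table
#'
#' Expects columns \code{sample_id}, \code{purity_consensus}, \code{ploidy};
#' optional \code{purity_absolute}, \code{purity_estimate}.
#'
#' @param path TSV (or CSV) file with a header.
#' @return data.frame.
#' @export
read_purity_table <- function(path) {
  df <- .read_table(path)
  .require_columns(df, c("sample_id", "purity_consensus", "ploidy"), path)
  for (col in intersect(c("purity_consensus", "ploidy", "purity_absolute",
                          "purity_estimate"), names(df)))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  df
}

# marker/logical parsing: accepts 0/1, true/false, TRUE/FALSE, +/-
.parse_bool <- function(v) {
  if (is.logical(v)) return(v)
  s <- tolower(trimws(as.character(v)))
  out <- rep(NA, length(s))
  out[s %in% c("1", "true", "t", "+", "yes")] <- TRUE
  out[s %in% c("0", "false", "f", "-", "−", "no")] <- FALSE
  if (any(is.na(out) & !is.na(v) & s != ""))
    stop("unrecognized boolean value(s): ",
         paste(unique(s[is.na(out) & s != ""]), collapse = ", "))
  out
}

#' Read a cell-coordinate table
#'
#' Expects \code{x_um}, \code{y_um} and at least one marker column; marker
#' values may be 0/1, true/false or +/-.
#'
#' @param path CSV or TSV file with a header.
#' @return data.frame with numeric coordinates and logical marker columns.
#' @export
read_cell_table <- function(path) {
  df <- .read_table(path)
  .require_columns(df, c("x_um", "y_um"), path)
  markers <- setdiff(names(df), c("x_um", "y_um", "phenotype"))
  if (!length(markers))
    stop("cell table '", path, "' has no marker columns")
  df$x_um <- as.numeric(df$x_um); df$y_um <- as.numeric(df$y_um)
  if (any(!is.finite(df$x_um)) || any(!is.finite(df$y_um)))
    stop("non-finite cell coordinates in ", path)
  for (m in markers) df[[m]] <- .parse_bool(df[[m]])
  df
}

#' Write a data.frame as TSV
#'
#' Canonical writer: tab-separated, header, no quoting, NA written as "NA",
#' logical columns written as 0/1.
#'
#' @param df data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(df, path) {
  for (col in names(df))
    if (is.logical(df[[col]])) df[[col]] <- as.integer(df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a run configuration
#'
#' Checks threshold domains and rejects unknown keys, so a typo cannot
#' silently fall back to a default.
#'
#' @param config named list; recognized keys: \code{min_purity},
#'   \code{max_disagreement}, \code{likely_clonal_min}, \code{loh_min},
#'   \code{two_copy_line}, \code{one_copy_line}, \code{clamp_max},
#'   \code{min_vaf}, \code{seed}.
#' @return the config with defaults filled in.
#' @export
validate_config <- function(config = list()) {
  defaults <- list(min_purity = 0.4, max_disagreement = 0.3,
                   likely_clonal_min = 0.4, loh_min = 0.9,
                   two_copy_line = -1.1, one_copy_line = -0.4,
                   clamp_max = 1.1, min_vaf = 0.1, seed = 1)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  in01 <- c("min_purity", "max_disagreement", "likely_clonal_min",
            "loh_min", "min_vaf")
  for (key in in01)
    if (!is.finite(cfg[[key]]) || cfg[[key]] < 0 || cfg[[key]] > 1)
      stop("config key '", key, "' must be in [0, 1]")
  if (cfg$clamp_max < 1) stop("clamp_max must be >= 1")
  if (cfg$two_copy_line >= cfg$one_copy_line)
    stop("two_copy_line must lie below one_copy_line")
  cfg
}

#' Run the purity/ploidy adjustment pipeline on table files
#'
#' Executes the full cohort analysis: purity filtering, copy-number and VAF
#' adjustment, clonality classification and cohort density summaries, writing
#' every output table plus a JSON manifest with input hashes and the
#' thresholds used. Rerunning with identical inputs and config reproduces the
#' manifest hashes.
#'
#' @param cn_file,variant_file,purity_file input tables (see the readers).
#' @param out_dir output directory (created if needed).
#' @param config threshold overrides, validated by [validate_config()].
#'
#' @return the manifest (named list), invisibly; written as
#'   \code{manifest.json} in \code{out_dir}.
#' @export
run_pipeline <- function(cn_file, variant_file, purity_file, out_dir,
                         config = list()) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cn <- read_copy_number_table(cn_file)
  variants <- read_variant_table(variant_file)
  purity <- read_purity_table(purity_file)

  filt <- consensus_purity_filter(purity, min_purity = cfg$min_purity,
                                  max_disagreement = cfg$max_disagreement)
  kept_ids <- filt$kept$sample_id

  cn <- cn[cn$sample_id %in% kept_ids, , drop = FALSE]
  idx <- match(cn$sample_id, filt$kept$sample_id)
  adj_cn <- adjust_copy_number(cn$cnr, filt$kept$purity_consensus[idx],
                               filt$kept$ploidy[idx])
  cn_out <- cbind(cn, adj_cn)
  ok_cn <- cn_out$status == "ok"
  cn_out$copy_loss_call <- NA_character_
  cn_out$copy_loss_call[ok_cn] <- as.character(classify_copy_loss(
    cn_out$cnr_adj[ok_cn], cfg$two_copy_line, cfg$one_copy_line))

  variants <- variants[variants$sample_id %in% kept_ids, , drop = FALSE]
  vidx <- match(variants$sample_id, filt$kept$sample_id)
  key <- paste(variants$sample_id, variants$gene)
  cn_key <- paste(cn_out$sample_id, cn_out$gene)
  cn_for_variant <- cn_out$cn_t[match(key, cn_key)]
  has_cn <- !is.na(cn_for_variant) & cn_for_variant > 0
  v_out <- variants
  v_out$cn_t <- cn_for_variant
  v_out$af_adj <- NA_real_
  v_out$clamped <- NA
  v_out$status <- ifelse(has_cn, "ok", "removed_incompatible")
  if (any(has_cn)) {
    adj_v <- adjust_vaf(variants$vaf[has_cn],
                        filt$kept$purity_consensus[vidx][has_cn],
                        cn_for_variant[has_cn], clamp_max = cfg$clamp_max)
    v_out$af_adj[has_cn] <- adj_v$af_adj
    v_out$clamped[has_cn] <- adj_v$clamped
    v_out$status[has_cn] <- adj_v$status
  }
  ok_v <- v_out$status == "ok"
  v_out$clonality_call <- NA_character_
  v_out$clonality_call[ok_v] <- as.character(classify_variant_clonality(
    v_out$af_adj[ok_v], cfg$likely_clonal_min, cfg$loh_min))

  files <- list(
    adjusted_copy_number = "adjusted_copy_number.tsv",
    adjusted_variants = "adjusted_variants.tsv",
    removed_samples = "removed_samples.tsv",
    cnr_density = "cnr_density.tsv",
    vaf_density = "vaf_density.tsv")
  write_tsv(cn_out, file.path(out_dir, files$adjusted_copy_number))
  write_tsv(v_out, file.path(out_dir, files$adjusted_variants))
  write_tsv(filt$removed, file.path(out_dir, files$removed_samples))
  cnr_vals <- cn_out$cnr_adj[ok_cn]
  if (sum(!is.na(cnr_vals)) >= 2) {
    dens <- cohort_density(cnr_vals)
    write_tsv(dens$grid, file.path(out_dir, files$cnr_density))
  } else files$cnr_density <- NULL
  vaf_vals <- v_out$af_adj[ok_v]
  if (sum(!is.na(vaf_vals)) >= 2) {
    dens <- cohort_density(vaf_vals)
    write_tsv(dens$grid, file.path(out_dir, files$vaf_density))
  } else files$vaf_density <- NULL

  outputs <- unlist(files)
  in_hash <- tools::md5sum(c(cn_file, variant_file, purity_file))
  names(in_hash) <- basename(names(in_hash))
  out_hash <- tools::md5sum(file.path(out_dir, outputs))
  names(out_hash) <- basename(names(out_hash))
  manifest <- list(
    config = cfg,
    inputs = as.list(in_hash),
    outputs = as.list(out_hash),
    n_samples_kept = length(kept_ids),
    n_samples_removed = nrow(filt$removed),
    removal_reasons = as.list(table(filt$removed$reason)),
    n_variants_removed_incompatible = sum(v_out$status ==
                                            "removed_incompatible"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
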
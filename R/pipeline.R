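# End-to-end orchestration: read -> moments -> G0/E(G0) -> tabular extension
# -> H^-1 / Dk / segregation summary, with every artifact written to disk and
# listed in a checksummed manifest so runs are reproducible and resumable.

.default_config <- function() {
  list(pedigree = NULL, genotypes = NULL, format = "csv", map = NULL,
       weights = NULL, alpha = 0.98, partitions = c("autosomal", "x"),
       genedrop_replicates = 0, seed = 1, out_dir = "crossgrm_out",
       male_het_x = "error", missing = "error", on_singular_h = "error")
}

#' Run the full relationship-matrix pipeline
#'
#' Reads pedigree and founder genotypes, computes line frequencies, gamete
#' moments, observed and expected founder matrices, blends, extends through
#' the pedigree, assembles the combined inverse, and writes reports (marker
#' classification, moments, rank, segregation summary for two-line crosses,
#' Dk) plus a machine-readable manifest with md5 checksums.  Optionally runs
#' a gene-drop validation.
#'
#' @param config named list overriding the defaults: `pedigree`, `genotypes`
#'   (paths), `format` ("csv"/"ped_map"), `map`, `weights`, `alpha`,
#'   `partitions`, `genedrop_replicates` (0 = skip), `seed`, `out_dir`,
#'   `male_het_x`, `missing`.  May also be the path of a flat `key = value`
#'   config file.
#' @return invisibly, the manifest (data frame of artifact paths and
#'   checksums).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- read_config(config)
  cfg <- utils::modifyList(.default_config(), config)
  if (is.null(cfg$pedigree) || is.null(cfg$genotypes))
    stop("config_missing_paths: pedigree and genotypes are required")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  paths <- character(0)
  emit <- function(name, writer) {
    p <- file.path(cfg$out_dir, name)
    writer(p)
    paths[[name]] <<- p
  }

  ped <- stage("read-pedigree", read_pedigree(cfg$pedigree))
  g <- stage("read-genotypes",
             read_founder_genotypes(cfg$genotypes, ped, format = cfg$format,
                                    map_path = cfg$map,
                                    male_het_x = cfg$male_het_x,
                                    missing = cfg$missing))
  freqs <- stage("moments", line_frequencies(g, weights = cfg$weights))
  lc <- line_composition(ped)

  cls <- stage("report", classify_markers(g))
  emit("marker_classification.tsv", function(p) {
    rows <- do.call(rbind, lapply(names(cls), function(part) {
      data.frame(partition = part,
                 all_founders = cls[[part]]$all_founders,
                 line_specific = cls[[part]]$line_specific,
                 t(cls[[part]]$within_line))
    }))
    utils::write.table(rows, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  moments_list <- list()
  report <- list(seed = cfg$seed, alpha = cfg$alpha)
  for (part in intersect(cfg$partitions, c("autosomal", "x"))) {
    if (is.null(freqs[[part]])) next
    tag <- if (part == "x") "x" else "autosomal"
    mom <- stage("moments", gametic_moments(freqs, part))
    moments_list[[tag]] <- mom
    g0 <- stage("grm-observed", observed_grm(g, freqs, part))
    e0 <- stage("grm-expected", expected_founder_grm(ped, mom))
    g0b <- stage("grm-observed", blend_grm(g0, e0, cfg$alpha))
    ext <- if (part == "autosomal")
      stage("extend", extend_autosomal(ped, e0, mom, lc))
    else stage("extend", extend_x(ped, e0, mom, lc))
    hinv <- if (identical(cfg$on_singular_h, "skip")) {
      tryCatch(build_h_inverse(ext, g0b, e0), error = function(e) {
        report[[paste0("hinv_", tag, "_error")]] <<- conditionMessage(e)
        NULL
      })
    } else {
      stage("build-h", build_h_inverse(ext, g0b, e0))
    }

    emit(sprintf("g0_%s.txt", tag), function(p) write_grm_dense(g0, p))
    emit(sprintf("e0_%s.txt", tag), function(p) write_grm_dense(e0, p))
    emit(sprintf("g0_blended_%s.txt", tag),
         function(p) write_grm_dense(g0b, p))
    emit(sprintf("atilde_%s.txt", tag), function(p) write_grm_dense(ext, p))
    if (!is.null(hinv))
      emit(sprintf("hinv_%s.txt", tag),
           function(p) write_grm_triplet(hinv$hinv, p))

    report[[paste0("rank_g0_", tag)]] <- grm_rank(g0)
    report[[paste0("dk_", tag)]] <- dk_correction(g0b)
    if (length(freqs$lines) == 2 &&
        max(abs(freqs$weights - 0.5)) <= 1e-12) {
      f2 <- f2_reference_summary(mom)
      report[[paste0("segregation_proportion_", tag)]] <-
        f2$segregation_proportion
      report[[paste0("f2_mean_self_", tag)]] <- f2$mean_self
    }
    if (cfg$genedrop_replicates > 0) {
      gd <- stage("genedrop",
                  gene_drop_grm(ped, g, freqs, part,
                                replicates = cfg$genedrop_replicates,
                                seed = cfg$seed, founder_source = "hwe"))
      emit(sprintf("genedrop_mean_%s.txt", tag),
           function(p) write_grm_dense(gd$mean, p))
      emit(sprintf("genedrop_se_%s.txt", tag),
           function(p) write_grm_dense(gd$se, p))
    }
    # generation means of diagonal self-relationships (diagnostic TSV)
    emit(sprintf("generation_means_%s.tsv", tag), function(p) {
      d <- diag(unclass(ext))
      df <- data.frame(generation = ped$generation, sex = ped$sex, self = d)
      agg <- stats::aggregate(self ~ generation + sex, df, mean)
      utils::write.table(agg[order(agg$generation, agg$sex), ], p,
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }
  emit("moments.tsv", function(p) write_moments_report(moments_list, p))
  emit("report.json", function(p)
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA))
  emit("config.json", function(p)
    jsonlite::write_json(cfg, p, auto_unbox = TRUE, digits = NA, null = "null"))

  manifest <- data.frame(artifact = names(paths),
                         path = unname(unlist(paths)),
                         md5 = unname(tools::md5sum(unlist(paths))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a flat key = value configuration file
#'
#' INI-style lines `key = value`; `#` starts a comment.  Values that parse
#' as numbers become numeric; comma-separated values become vectors.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("config_malformed_line: ", l)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}
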
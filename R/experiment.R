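#' Run an end-to-end puncta experiment
#'
#' Drives the whole chain for every cell of a configured cohort: read the
#' stack, run the puncta pipeline per channel, profile size classes, measure
#' the peripheral fraction of large puncta, optionally correlate two
#' channels, then compare groups with reference normalization. All outputs
#' (per-cell puncta CSVs, long-format metrics, size profiles, group report)
#' are written under `config$out_dir` together with a manifest listing every
#' file with its MD5 hash. Given fixed inputs and seed the numeric outputs
#' are byte-identical across reruns.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list: `metrics` (long per-cell tibble), `profiles`,
#'   `periphery`, `coloc`, `group_results` (list of `group_result`),
#'   `manifest`.
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config.")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  missing <- !file.exists(config$cells$path)
  if (any(missing)) {
    abort(sprintf("unreadable input(s): %s.",
                  paste(config$cells$path[missing], collapse = ", ")))
  }
  scheme <- size_scheme(config$scheme_name)
  metrics <- list(); profiles <- list(); periphery <- list(); coloc <- list()
  for (i in seq_len(nrow(config$cells))) {
    cell <- config$cells[i, ]
    chans <- read_image_stack(cell$path, config$um_per_pixel)
    use <- config$channels %||% names(chans)
    tables <- list()
    for (ch in use) {
      if (!ch %in% names(chans)) {
        abort(sprintf("channel '%s' not present in %s.", ch, cell$path))
      }
      tab <- run_pipeline(chans[[ch]], config$pipeline,
                          image_id = cell$cell_id)
      tables[[ch]] <- tab
      write_puncta_csv(tab, file.path(
        config$out_dir, sprintf("puncta_%s_%s.csv", cell$cell_id, ch)))
      prof <- classify_puncta(tab, scheme, cell_id = cell$cell_id)
      profiles[[paste(cell$cell_id, ch, sep = "_")]] <-
        mutate(as_tibble(prof), cell_id = cell$cell_id, group = cell$group,
               channel = ch)
      flat <- overlay_stack(chans[[ch]], config$pipeline$projection)
      geom <- peripheral_band(estimate_cell_mask(flat), config$band_width_um)
      pf <- peripheral_fraction(tab, geom, config$min_large_area_um2)
      periphery[[paste(cell$cell_id, ch, sep = "_")]] <-
        mutate(pf, cell_id = cell$cell_id, group = cell$group, channel = ch)
      named <- scheme[!grepl("^\\(", scheme$class), ]
      metrics[[paste(cell$cell_id, ch, sep = "_")]] <- bind_rows(
        tibble(metric = "total_puncta", value = nrow(tab)),
        tibble(metric = paste0("n_", named$class),
               value = vapply(seq_len(nrow(named)), function(j) {
                 as.numeric(count_in_range(
                   tab, named$lower_um2[j], named$upper_um2[j],
                   lower_closed = named$lower_closed[j],
                   upper_closed = named$upper_closed[j]))
               }, 1)),
        tibble(metric = "n_large", value = sum(tab$area_um2 >
                                                 config$min_large_area_um2)),
        tibble(metric = "peripheral_fraction", value = pf$fraction)
      ) |> mutate(cell_id = cell$cell_id, group = cell$group, channel = ch)
    }
    if (!is.null(config$coloc_channels)) {
      cc <- config$coloc_channels
      f1 <- overlay_stack(chans[[cc[1]]], config$pipeline$projection)
      f2 <- overlay_stack(chans[[cc[2]]], config$pipeline$projection)
      geom <- estimate_cell_mask(f1)
      res <- pearson_no_threshold(
        to_eight_bit(f1), to_eight_bit(f2), roi = geom,
        tophat_radius_px = config$pipeline$tophat_radius_px)
      big <- coloc_in_large_puncta(to_eight_bit(f1), to_eight_bit(f2),
                                   tables[[cc[1]]],
                                   config$min_large_area_um2)
      coloc[[cell$cell_id]] <- mutate(
        bind_rows(res, big), cell_id = cell$cell_id, group = cell$group)
      metrics[[paste(cell$cell_id, "coloc", sep = "_")]] <- tibble(
        metric = c("pearson_cell", "pearson_large_puncta"),
        value = c(res$pearson_r, big$pearson_r),
        cell_id = cell$cell_id, group = cell$group, channel = "pair")
    }
  }
  metrics <- bind_rows(metrics)
  profiles <- bind_rows(profiles)
  periphery <- bind_rows(periphery)
  coloc <- if (length(coloc)) bind_rows(coloc) else NULL
  group_results <- summarize_groups(metrics, config$reference)
  write.csv(metrics, file.path(config$out_dir, "metrics_long.csv"),
            row.names = FALSE)
  write.csv(profiles, file.path(config$out_dir, "size_profiles.csv"),
            row.names = FALSE)
  write.csv(periphery, file.path(config$out_dir, "periphery.csv"),
            row.names = FALSE)
  if (!is.null(coloc)) {
    write.csv(coloc, file.path(config$out_dir, "coloc.csv"),
              row.names = FALSE)
  }
  write_group_report(group_results,
                     file.path(config$out_dir, "group_report.csv"))
  manifest <- write_manifest(config)
  invisible(list(metrics = metrics, profiles = profiles,
                 periphery = periphery, coloc = coloc,
                 group_results = group_results, manifest = manifest))
}

# one comparison per metric; t-test for 2 groups, ANOVA + Tukey for more
summarize_groups <- function(metrics, reference) {
  out <- list()
  for (m in unique(metrics$metric)) {
    sub <- metrics[metrics$metric == m & is.finite(metrics$value), ]
    ok <- table(sub$group)
    if (length(ok) < 2 || any(ok < 2)) next
    # degenerate metrics (e.g. all values identical) cannot be tested
    res <- tryCatch({
      if (length(ok) == 2) {
        compare_two_groups(sub, value, group, reference = reference)
      } else {
        compare_many_groups(sub, value, group, reference = reference)
      }
    }, error = function(e) NULL)
    if (!is.null(res)) out[[m]] <- res
  }
  out
}

write_group_report <- function(group_results, path) {
  rows <- imap(group_results, function(res, metric) {
    s <- tidy(res)
    s$metric <- metric
    s$test <- res$test
    s$statistic <- res$statistic
    s$p_value <- res$p_value
    s$significance <- trimws(significance_marker(res$p_value))
    s
  })
  write.csv(bind_rows(rows), path, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(config) {
  files <- sort(setdiff(list.files(config$out_dir, full.names = TRUE),
                        file.path(config$out_dir, "manifest.json")))
  manifest <- list(
    config = config_as_list(config),
    outputs = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$cells <- as.data.frame(out$cells)
  out$pipeline <- unclass(out$pipeline)
  out
}

#' Simulate a two-group cohort on disk
#'
#' Writes synthetic "young"-like and "aged"-like cells as TIFF stacks with
#' ground-truth sidecars and returns a ready [run_config()]. The aged group
#' is generated with fewer small (lysosome-range) puncta, fewer
#' autophagosome-range puncta, more large (>10 um^2) puncta, and a stronger
#' peripheral bias of the large puncta — the planted phenotype the group
#' statistics should recover.
#'
#' @param dir Directory for the TIFFs and config.
#' @param n_per_group Cells per group.
#' @param acq An [acquisition_params()].
#' @param seed Integer seed.
#' @param young,aged Named lists with `n_lysosome`, `n_autophagosome`,
#'   `n_large`, `peripheral_bias` overriding the per-group defaults.
#' @param threshold Pipeline threshold recorded in the config (default 120,
#'   about half the rendered punctum amplitude after top-hat).
#' @return A `run_config` for [run_experiment()].
#' @export
simulate_cohort <- function(dir, n_per_group = 6,
                            acq = acquisition_params(),
                            seed = 1L,
                            young = list(n_lysosome = 60, n_autophagosome = 25,
                                         n_large = 2, peripheral_bias = 0.3),
                            aged = list(n_lysosome = 40, n_autophagosome = 15,
                                        n_large = 6, peripheral_bias = 0.8),
                            threshold = 120) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  groups <- list(young = young, aged = aged)
  cells <- list()
  k <- 0L
  for (g in names(groups)) {
    p <- groups[[g]]
    for (j in seq_len(n_per_group)) {
      k <- k + 1L
      cell_id <- sprintf("%s_%02d", g, j)
      sim <- generate_peripheral_cohort(
        n_large_puncta = p$n_large, peripheral_bias = p$peripheral_bias,
        acq = acq, seed = seed * 1000L + k,
        small_spec = puncta_spec(
          n = c(p$n_lysosome, p$n_autophagosome),
          lower_um2 = c(0.03, 0.196), upper_um2 = c(0.5, 1.767)))
      path <- file.path(dir, paste0(cell_id, ".tif"))
      write_image_stack(list(ch1 = sim$stack), path,
                        ground_truth = sim$truth)
      cells[[k]] <- tibble(cell_id = cell_id, group = g, path = path)
    }
  }
  run_config(cells = bind_rows(cells),
             out_dir = file.path(dir, "results"),
             reference = "young",
             pipeline = pipeline_params(threshold = threshold),
             scheme_name = "lc3b", seed = seed)
}

#' Render a QC overlay figure
#'
#' Writes a PNG of the projected image with detected puncta outlined at
#' their equivalent radius, the peripheral band boundary, and a 10-um scale
#' bar, for visual inspection of a run.
#'
#' @param img A projected `calibrated_image`.
#' @param table A `puncta_table` for that image.
#' @param geom A `cell_geometry` (band optional).
#' @param path Output PNG path.
#' @param band_width_um Band width when `geom` carries none.
#' @return `path`, invisibly.
#' @export
render_qc <- function(img, table, geom = NULL, path, band_width_um = 10) {
  stopifnot_image(img)
  upx <- img$um_per_pixel
  df <- tibble(
    x = rep((seq_len(ncol(img$pixels)) - 1) * upx,
            each = nrow(img$pixels)),
    y = rep((seq_len(nrow(img$pixels)) - 1) * upx,
            times = ncol(img$pixels)),
    value = as.vector(img$pixels))
  p <- ggplot(df, aes(.data$x, .data$y)) +
    geom_raster(aes(fill = .data$value)) +
    scale_fill_viridis_c(guide = "none") +
    coord_equal(expand = FALSE) +
    labs(x = "x (um)", y = "y (um)") +
    theme_minimal()
  if (nrow(table) > 0) {
    p <- p + ggplot2::geom_path(
      data = circle_paths(table$centroid_x_um, table$centroid_y_um,
                          table$equivalent_diameter_um / 2,
                          table$label),
      aes(.data$x, .data$y, group = .data$id), colour = "red",
      linewidth = 0.3)
  }
  if (!is.null(geom)) {
    if (is.null(geom$band_mask)) geom <- peripheral_band(geom, band_width_um)
    edge <- mask_boundary(geom$band_mask & geom$cell_mask, upx)
    inner <- mask_boundary(geom$cell_mask & !geom$band_mask, upx)
    p <- p + geom_point(data = bind_rows(edge, inner), aes(.data$x, .data$y),
                        colour = "white", size = 0.05)
  }
  # 10-um scale bar, lower-left corner
  x0 <- 0.05 * max(df$x); y0 <- 0.95 * max(df$y)
  p <- p + ggplot2::annotate("segment", x = x0, xend = x0 + 10, y = y0,
                             yend = y0, colour = "white", linewidth = 1.2)
  ggplot2::ggsave(path, p, width = 6, height = 6, dpi = 150)
  invisible(path)
}

circle_paths <- function(cx, cy, r, id, n = 48) {
  th <- seq(0, 2 * pi, length.out = n)
  bind_rows(lapply(seq_along(cx), function(i) {
    tibble(id = id[i], x = cx[i] + r[i] * cos(th), y = cy[i] + r[i] * sin(th))
  }))
}

# 4-neighbour boundary pixels of a mask, as micron coordinates
mask_boundary <- function(mask, upx) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  interior <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  edge <- which(mask & !interior)
  tibble(x = (((edge - 1) %/% nr)) * upx, y = (((edge - 1) %% nr)) * upx)
}
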
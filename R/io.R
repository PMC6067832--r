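#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the resolved configuration,
#' seed, per-phase iteration counts, package version, and an inventory of
#' output files with sizes.
#'
#' @param dir Run output directory.
#' @param config Resolved configuration list.
#' @param seed Integer seed.
#' @param phases Data frame of phases (name, iterations).
#' @param extra Optional named list merged into the manifest.
#' @return Path to `manifest.json`, invisibly.
#' @export
writeManifest <- function(dir, config, seed, phases = NULL, extra = list()) {
  files <- setdiff(list.files(dir), "manifest.json")
  man <- c(list(
    package = "gcalsim",
    version = as.character(utils::packageVersion("gcalsim")),
    seed = seed,
    config = config,
    phases = phases,
    files = data.frame(
      file = files,
      bytes = vapply(file.path(dir, files),
                     function(f) as.numeric(file.size(f)), numeric(1)))),
    extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# hue-coded orientation image: hue = preference / pi, value = optional
# activation weighting, grey where preference is undefined
orientationRGB <- function(pref, value = NULL) {
  h <- pref / pi
  v <- if (is.null(value)) matrix(1, nrow(pref), ncol(pref))
       else value / max(value, 1e-12)
  bad <- !is.finite(h)
  h[bad] <- 0; v[bad] <- 0.5
  cols <- grDevices::hsv(pmin(pmax(h, 0), 1), ifelse(bad, 0, 1),
                         pmin(pmax(v, 0), 1))
  rgb <- grDevices::col2rgb(cols) / 255
  arr <- array(0, dim = c(nrow(pref), ncol(pref), 3))
  arr[, , 1] <- matrix(rgb[1, ], nrow(pref))
  arr[, , 2] <- matrix(rgb[2, ], nrow(pref))
  arr[, , 3] <- matrix(rgb[3, ], nrow(pref))
  arr
}

#' Render a report directory from protocol results
#'
#' Writes, for each result bundle: the contrast-response table as CSV, a
#' contrast-response line plot per spatial frequency (all models overlaid),
#' orientation-preference PNG maps (hue = preferred angle), activation maps
#' for the low- and medium-SF 80%-contrast gratings, combined
#' preference-times-activation maps, tuning-histogram plots, and an
#' orientation key.  Missing measurements produce an explicit `MISSING_*`
#' marker file rather than a silent omission.
#'
#' @param results Named list of bundles from [runProtocol()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
renderReport <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (length(results) == 0) {
    writeLines("no data: empty results bundle",
               file.path(dir, "MISSING_results.txt"))
    return(invisible(dir))
  }
  if (is.null(names(results)) || any(names(results) == ""))
    names(results) <- paste0("model_", seq_along(results))
  # combined contrast-response CSV and per-SF line plots
  crs <- list()
  for (nm in names(results)) {
    cr <- results[[nm]]$contrast_response
    if (is.null(cr)) {
      writeLines(paste("no data: contrast response missing for", nm),
                 file.path(dir, paste0("MISSING_contrast_", nm, ".txt")))
      next
    }
    cr$model <- nm
    crs[[nm]] <- cr
    utils::write.csv(cr, file.path(dir, paste0("contrast_", nm, ".csv")),
                     row.names = FALSE)
  }
  if (length(crs)) {
    all_cr <- do.call(rbind, crs)
    utils::write.csv(all_cr, file.path(dir, "contrast_response.csv"),
                     row.names = FALSE)
    for (sfv in sort(unique(all_cr$sf))) {
      f <- file.path(dir, sprintf("contrast_response_sf%g.png", sfv))
      grDevices::png(f, width = 640, height = 480)
      sub <- all_cr[all_cr$sf == sfv, ]
      graphics::plot(NULL, xlim = range(sub$contrast),
                     ylim = c(0, max(sub$mean_activation) * 1.05),
                     xlab = "contrast", ylab = "mean V1 activation",
                     main = sprintf("%g cycles/image", sfv), log = "x")
      mods <- unique(sub$model)
      for (i in seq_along(mods)) {
        s <- sub[sub$model == mods[i], ]
        s <- s[order(s$contrast), ]
        graphics::lines(s$contrast, s$mean_activation, col = i,
                        lwd = if (i == 1) 3 else 1.5)
        graphics::points(s$contrast, s$mean_activation, col = i, pch = 19)
      }
      graphics::legend("topleft", legend = mods, col = seq_along(mods),
                       lwd = 2, bty = "n")
      grDevices::dev.off()
    }
  }
  for (nm in names(results)) {
    res <- results[[nm]]
    if (!is.null(res$orientation_map)) {
      map <- res$orientation_map
      png::writePNG(orientationRGB(map@preference),
                    file.path(dir, paste0("orientation_map_", nm, ".png")))
      if (!is.null(res$model)) {
        for (sfv in c(1.5, 6)) {
          img <- gratingStimulus(sfv, 0.8, model = res$model)
          act <- presentStimulus(res$model, img)$v1
          a <- act / max(act, 1e-12)
          png::writePNG(a, file.path(dir, sprintf("activation_sf%g_%s.png",
                                                  sfv, nm)))
          if (sfv == 6)
            png::writePNG(orientationRGB(map@preference, act),
                          file.path(dir,
                                    paste0("preference_activation_", nm,
                                           ".png")))
        }
      }
    } else {
      writeLines(paste("no data: orientation map missing for", nm),
                 file.path(dir, paste0("MISSING_map_", nm, ".txt")))
    }
    if (!is.null(res$tuning)) {
      h <- res$tuning$histogram
      f <- file.path(dir, paste0("tuning_histogram_", nm, ".png"))
      grDevices::png(f, width = 640, height = 480)
      graphics::plot(h$mids, h$counts, type = "h", lwd = 4,
                     xlab = "orientation (rad)",
                     ylab = "activation-weighted count",
                     main = sprintf("%s (excess kurtosis %.3f)", nm,
                                    h$excess_kurtosis))
      graphics::abline(v = pi / 2, lty = 2)
      grDevices::dev.off()
      utils::write.csv(data.frame(orientation = h$mids, weight = h$counts),
                       file.path(dir, paste0("tuning_histogram_", nm,
                                             ".csv")),
                       row.names = FALSE)
    }
  }
  # orientation key (hue wheel strip)
  key <- matrix(seq(0, pi, length.out = 180), nrow = 20, ncol = 180,
                byrow = TRUE)
  png::writePNG(orientationRGB(key), file.path(dir, "orientation_key.png"))
  invisible(dir)
}
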
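## Shared fixtures: rendered traveling-wave recordings and their profiles.

## one beat cycle sampled by `frames_per_cycle` uniformly phased frames
render_cycle <- function(kappa0 = 0.05, amp = 0.10, frames_per_cycle = 8,
                         freq = 2, noise = 0.05, seed = 1, quantize = TRUE,
                         ...) {
  p <- wave_params(kappa0 = kappa0, amp = amp, freq_hz = freq,
                   fps = frames_per_cycle * freq, duration_s = 1 / freq,
                   noise_sigma_um = noise, seed = seed, ...)
  render_trace_set(p, flagellum_id = "cycle", quantize = quantize)
}

cycle_profiles <- function(ts, cfg = waveform_config()) {
  lapply(to_microns(ts)$traces, tangent_profile, step_px = cfg$step_px,
         window_px = cfg$window_px, pixel_size_um = cfg$pixel_size_um)
}

cycle_curvatures <- function(ts, cfg = waveform_config()) {
  lapply(to_microns(ts)$traces, curvature_profile,
         window_px = cfg$window_px, step_px = cfg$step_px,
         pixel_size_um = cfg$pixel_size_um)
}

recover_slope <- function(...) {
  fit_static_component(cycle_profiles(render_cycle(...)))$slope
}

## write a small trace CSV for io tests
write_trace_csv <- function(path, ids, frames, n_points = 50) {
  rows <- do.call(rbind, lapply(ids, function(id) {
    do.call(rbind, lapply(frames, function(f) {
      data.frame(flagellum_id = id, frame = f,
                 x = seq_len(n_points) * 10 + f,
                 y = rep(100, n_points) + seq_len(n_points) %% 7)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  rows
}

## minimal stored (uncompressed) ZIP writer: the image lacks a `zip`
## binary, and binary fixtures may not be stored in the repo, so archives
## for reader tests are built here at run time
crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(bitwShiftR(c, 1L), -306674912L)  # 0xEDB88320 as signed
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[i + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L
  for (b in as.integer(bytes)) {
    c <- bitwXor(bitwShiftR(c, 8L) |> bitwAnd(16777215L),
                 crc32_table[bitwAnd(bitwXor(c, b), 255L) + 1L])
  }
  bitwXor(c, -1L)
}

u32 <- function(v) writeBin(as.integer(v), raw(), size = 4,
                            endian = "little")
u16 <- function(v) writeBin(as.integer(v), raw(), size = 2,
                            endian = "little")

write_stored_zip <- function(zipfile, files) {
  entries <- list()
  offset <- 0L
  body <- raw(0)
  for (f in files) {
    dat <- readBin(f, "raw", file.info(f)$size)
    nm <- charToRaw(basename(f))
    crc <- crc32(dat)
    local_hdr <- c(u32(0x04034b50), u16(20), u16(0), u16(0), u16(0), u16(0),
                   u32(crc), u32(length(dat)), u32(length(dat)),
                   u16(length(nm)), u16(0), nm)
    entries[[f]] <- list(crc = crc, size = length(dat), nm = nm,
                         offset = offset)
    body <- c(body, local_hdr, dat)
    offset <- length(body)
  }
  cd <- raw(0)
  for (e in entries) {
    cd <- c(cd, u32(0x02014b50), u16(20), u16(20), u16(0), u16(0), u16(0),
            u16(0), u32(e$crc), u32(e$size), u32(e$size), u16(length(e$nm)),
            u16(0), u16(0), u16(0), u16(0), u32(0), u32(e$offset), e$nm)
  }
  eocd <- c(u32(0x06054b50), u16(0), u16(0), u16(length(entries)),
            u16(length(entries)), u32(length(cd)), u32(length(body)),
            u16(0))
  writeBin(c(body, cd, eocd), zipfile)
}

## minimal ImageJ .roi polyline writer (big-endian), for reader tests only
write_imagej_roi <- function(path, x, y) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("Iout", con, 4, eos = NULL)
  writeBin(227L, con, size = 2, endian = "big")            # version
  writeBin(as.raw(c(5L, 0L)), con)                         # polyline, pad
  top <- min(y); left <- min(x)
  writeBin(as.integer(c(top, left, max(y), max(x))), con,
           size = 2, endian = "big")
  writeBin(length(x), con, size = 2, endian = "big")
  writeBin(raw(64 - 18), con)                              # pad to offset 64
  writeBin(as.integer(x - left), con, size = 2, endian = "big")
  writeBin(as.integer(y - top), con, size = 2, endian = "big")
}
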
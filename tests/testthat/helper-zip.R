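# Minimal stored (uncompressed) zip writer, used only to create test
# archives for unpack_archive(); the environment ships an unzip tool but no
# zip tool, and binary fixtures cannot be checked in.

crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- as.integer(n)
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(bitwShiftR(c, 1L), -306674912L)  # 0xEDB88320
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   crc32_table[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

# relnames are stored as given (use "dir/file.txt" entries for folders).
make_stored_zip <- function(zipfile, root, relnames) {
  con <- file(zipfile, open = "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  offsets <- integer(0)
  metas <- list()
  pos <- 0L
  for (rel in relnames) {
    data <- readBin(file.path(root, rel), what = "raw",
                    n = file.info(file.path(root, rel))$size)
    crc <- crc32(data)
    name <- charToRaw(rel)
    offsets <- c(offsets, pos)
    metas[[length(metas) + 1]] <- list(name = name, crc = crc,
                                       size = length(data))
    w4(67324752); w2(20); w2(0); w2(0); w2(0); w2(33)  # local header
    w4(crc); w4(length(data)); w4(length(data))
    w2(length(name)); w2(0)
    writeBin(name, con)
    if (length(data)) writeBin(data, con)
    pos <- pos + 30L + length(name) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(metas)) {
    m <- metas[[i]]
    w4(33639248); w2(20); w2(20); w2(0); w2(0); w2(0); w2(33)
    w4(m$crc); w4(m$size); w4(m$size)
    w2(length(m$name)); w2(0); w2(0); w2(0); w2(0); w4(0)
    w4(offsets[i])
    writeBin(m$name, con)
    pos <- pos + 46L + length(m$name)
  }
  w4(101010256); w2(0); w2(0)
  w2(length(metas)); w2(length(metas))
  w4(pos - cd_start); w4(cd_start); w2(0)
  zipfile
}

# Zip up a generated archive directory; wrap = TRUE keeps the top-level
# folder inside the zip.
zip_archive_dir <- function(dir, wrap = FALSE) {
  zf <- tempfile(fileext = ".zip")
  files <- list.files(dir, recursive = TRUE)
  if (wrap) {
    make_stored_zip(zf, dirname(dir), file.path(basename(dir), files))
  } else {
    make_stored_zip(zf, dir, files)
  }
  zf
}
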
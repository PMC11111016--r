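# Minimal mzXML 3.2 writer for cross-format read tests (the package itself
# writes mzML through mzR, which has no mzXML writer). Peaks are uncompressed
# network-byte-order 64-bit m/z-intensity pairs.
write_toy_mzxml <- function(run, path) {
  enc <- function(mz, int) {
    if (!length(mz)) return("")
    raw <- writeBin(as.vector(rbind(mz, int)), raw(), size = 8,
                    endian = "big")
    jsonlite::base64_enc(raw)
  }
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(run$spectra)
  writeLines(c(
    '<?xml version="1.0" encoding="ISO-8859-1"?>',
    paste0('<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/',
           'mzXML_3.2">'),
    sprintf(' <msRun scanCount="%d">', n)), con)
  for (i in seq_len(n)) {
    s <- run$spectra[[i]]
    np <- length(s$mz)
    writeLines(sprintf(paste0(
      '  <scan num="%d" msLevel="%d" peaksCount="%d" retentionTime="PT%.6fS"',
      ' lowMz="%.4f" highMz="%.4f" totIonCurrent="%.4f">'),
      i, s$ms_level, np, s$rt * 60,
      if (np) min(s$mz) else 0, if (np) max(s$mz) else 0,
      sum(s$intensity)), con)
    writeLines(sprintf(paste0(
      '   <peaks precision="64" byteOrder="network" contentType="m/z-int"',
      ' compressionType="none" compressedLen="0">%s</peaks>'),
      enc(s$mz, s$intensity)), con)
    writeLines('  </scan>', con)
  }
  writeLines(c(' </msRun>', '</mzXML>'), con)
  invisible(path)
}
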
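# Shared fixture builders; all deterministic given an explicit seed.

# a RecognitionSite covering the central 10-bp window of a duplex scene
sceneSite <- function(scene, motifStart = 6L, motifLen = 4L, flankLeft = 3L) {
  pairing <- scene$topology@pairing
  win <- (motifStart - flankLeft):(motifStart - flankLeft + 9L)
  new("RecognitionSite", id = 1L, motif = "GCGC",
      scaffoldIdx = as.integer(motifStart:(motifStart + motifLen - 1L)),
      stapleIdx = pairing[motifStart:(motifStart + motifLen - 1L)],
      windowScaffoldIdx = as.integer(win),
      windowStapleIdx = pairing[win],
      pathStart = as.integer(motifStart), truncated = FALSE,
      crossoverOverlap = FALSE, substructure = "")
}

# fixed-width PDB ATOM records from a data.frame with columns
# name, alt, resn, chain, resno, x, y, z, elem (coordinates in Angstrom)
writePdbFixture <- function(path, df) {
  lines <- vapply(seq_len(nrow(df)), function(i) {
    sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, df$name[i], df$alt[i], df$resn[i], df$chain[i], df$resno[i],
            df$x[i], df$y[i], df$z[i], 1, 0, df$elem[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# apply one rigid motion to every frame of a trajectory
transformTrajectory <- function(traj, rotation, translation) {
  tf <- rigidTransform(rotation, translation)
  for (t in seq_len(nFrames(traj))) {
    traj@positions[, , t] <- applyTransform(tf, traj@positions[, , t])
    traj@bbVersors[, , t] <- applyTransform(tf, traj@bbVersors[, , t], rotateOnly = TRUE)
    traj@normVersors[, , t] <- applyTransform(tf, traj@normVersors[, , t], rotateOnly = TRUE)
  }
  traj
}

# gap ladder used by the raft known-answer scenes: values keep clear of the
# analytic block/clear threshold (2.6 nm for a 3 nm probe) by >= 0.6 nm
raftGapLadder <- function() c(0.5, 1, 1.5, 2, 3.2, 4, 5, 6, 8, 10)
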
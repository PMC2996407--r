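# Label table on-disk layout (`motifhash-table-1`)

A label table is a hierarchical directory store: one group of datasets per
target plus one dataset per label key, with a JSON metadata header.  All
datasets are plain TSV (gzip-compressed where marked), so the format is
portable across languages.

```
<table>/
  meta.json                       # header (see below)
  targets/
    <target_id>.residues.tsv.gz   # one row per residue, in structure order:
                                  # chain_id  seq_number  insertion_code
                                  # label  ca_x ca_y ca_z  cen_x cen_y cen_z
                                  # cen_fallback  depth        (Angstrom)
    <target_id>.counts.tsv        # label  count   (residue label frequencies)
    <target_id>.neighbors.tsv.gz  # i  j  dist: all ordered pairs with
                                  # dist <= neighbor_radius_2r, grouped by i,
                                  # ascending dist within each i
  keys/
    <KEY>.tsv.gz                  # KEY = sorted one-letter labels
                                  # concatenated (e.g. DHK); columns:
                                  # target_id  i1 .. in
```

`meta.json` fields: `schema` (`"motifhash-table-1"`), `codec` (compression
of the `.gz` datasets, `"gzip"`), `neighbor_radius_2r` (Angstrom),
`params` (the reference-set geometric parameters used at build time:
`n`, `d_maxmindist`, `d_diameter`, `d_maxdepth`, `d_maxmindepth`,
`check_depth`), `targets` (stored ids), `skipped` (ids that failed
preprocessing).

Each `keys/<KEY>` matrix stores every reference set whose sorted label
tuple equals `KEY`, one row per set; `i1..in` are 1-based indices into the
target's residue table (rows of `<target_id>.residues.tsv.gz`).  Rows are
grouped into contiguous blocks per target; the `target_id` column is the
row-block index mapping blocks to targets.  A lookup therefore touches only
`meta.json` and the single requested key dataset.

Matching a query's geometric parameters against `params` is mandatory:
reference sets enumerated under different parameters are not comparable,
and mixing them silently invalidates the missed-match statistics.
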
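# fieldplotr

Serpentine field-trial plot layouts as georeferenced polygon layers.

Plot-level remote sensing and UAV high-throughput phenotyping need a vector
layer that demarcates every experimental plot, so per-plot statistics can be
extracted from imagery. `fieldplotr` builds that layer straight from the way
a trial is described on paper: a `rows x ranges` footprint walked in
serpentine (boustrophedon) order from the bottom-left cell, with

* **replicate-prefixed numbering** for replicated designs
  (`rep * 10^d + i`, `d = max(2, digits(plots_per_rep))`: three reps of 20
  plots are 101–120, 201–220, 301–320; of 200 plots, 1001–1200, 2001–2200,
  3001–3200) and sequential `start..end` numbering for unreplicated ones;
* **fill plots** after each replicate and whole **irrigation wheel-track
  ranges**, both removed from the output layer;
* a **plot indent** for nurseries that start mid-range, and excluded cells
  after the last plot;
* per-axis **canopy buffers**: each total plot dimension is reduced by
  twice its buffer, keeping the region of interest centred in its cell;
* a **field-book CSV join** by plot number (no field-map intermediate);
* export to **ESRI Shapefile** (`.shp/.shx/.dbf/.prj`) or deterministic
  **GeoJSON**, in any projected or local metre/foot CRS.

## Worked example

The built-in case study is a replicated yield trial: 3 replicates of 30
plots, two fills after each replicate, wheel tracks in ranges 9 and 18, on
a 4 x 26 footprint of 20 x 10 ft plots trimmed by 5 / 2.5 ft buffers.

```r
library(fieldplotr)

cs1 <- case_study_1()
cs1$spec
#> Replicated serpentine layout 'yield_trial'
#>   3 reps x 30 plots, footprint 4 rows x 26 ranges
#>   fills after reps: 2,2,2; wheel-track ranges: 9,18; direction: left-to-right
#>   specified plots: 104 / total possible: 104

m   <- build_matrix(cs1$spec)
tab <- join_attributes(
  build_feature_table(m, cs1$dims,
                      placement(origin = c(443000, 4650000), crs = "EPSG:32614")),
  cs1$book)
tab
#> Plot feature table: 90 features (plot, rep, name, pedigree)
#> CRS: PROJCS["WGS 84 / UTM zone 14N",GEOGCS["WGS 84",DATUM["WGS_19 ...

head(as.data.frame(tab)[, 1:4], 3)
#>   plot rep      name      pedigree
#> 1  101   1 LINE_0001   AMBER/DELTA
#> 2  102   1 LINE_0002    BASIN/GALE
#> 3  103   1 LINE_0003 CREST/JUNIPER

basename(write_layer(tab, file.path(tempdir(), "yield_trial")))
#> [1] "yield_trial.shp" "yield_trial.shx" "yield_trial.dbf" "yield_trial.prj"
```

The 104 specified plots (90 experimental + 6 fills + 8 wheel-track cells)
exactly fill the 104-cell footprint; only the 90 experimental plots become
features, each a 10 x 5 ft rectangle centred in its 20 x 10 ft cell and
carrying the line name and pedigree joined from the field book by plot
number. The ASCII preview shows any matrix the same way a field map is
read, front range at the bottom:

```r
cat(render_preview(build_matrix(unreplicated_spec(101, 112, rows = 4, ranges = 3))),
    sep = "\n")
#> 109 110 111 112
#> 108 107 106 105
#> 101 102 103 104
```

## Command line

The same pipeline is scriptable via `inst/cli/fieldplotr` (or
`fieldplotr::cli_main()`):

```sh
fieldplotr replicated --plots-per-rep 30 --reps 3 --rows 4 --ranges 26 \
  --fills 2,2,2 --wheel-tracks 9,18 \
  --plot-length 20 --plot-width 10 --length-buffer 5 --width-buffer 2.5 \
  --units english --fieldbook book.csv --output yield_trial
```

`--preview` prints the ASCII map (with `F`/`W`/`.` for fill, wheel-track
and excluded cells), validation problems go to standard error with a
nonzero exit, and `--config layout.yaml` can supply any flag's value under
its underscored name. `fieldplotr unreplicated` covers nurseries
(`--start-plot/--end-plot/--indent`).

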
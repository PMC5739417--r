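# Netlist JSON format

A chip netlist is a single JSON object with the following top-level keys.

```json
{
  "units": "um",
  "fluid": {"viscosity": 1e-3, "density": 998},
  "nodes": {
    "id":   ["IN", "J1", "OUT"],
    "kind": ["terminal", "intersection", "terminal"],
    "x":    [0, 800, 1600],
    "y":    [0, 0, 0]
  },
  "segments": {
    "id":     ["s1", "s2"],
    "from":   ["IN", "J1"],
    "to":     ["J1", "OUT"],
    "width":  [200, 200],
    "height": [100, 100],
    "waypoints": [[], []]
  },
  "boundary_conditions": {
    "terminal": ["IN", "OUT"],
    "type":     ["velocity", "pressure"],
    "value":    [0.01, 0]
  }
}
```

Keys:

- `units` — unit of **all geometric lengths** (`"m"`, `"mm"` or `"um"`);
  converted to meters on load. Pressures are always Pa and velocities
  always m/s regardless of this setting.
- `fluid` — dynamic `viscosity` (Pa s) and `density` (kg/m^3); defaults
  describe water (1e-3, 998) when omitted.
- `nodes` — node `id`, `kind` (`terminal` | `turn` | `intersection`) and
  planar center position `x`, `y`. Terminals attach exactly one segment,
  turns exactly two, intersections three or four (each on a distinct
  compass arm N/E/S/W).
- `segments` — rectangular channels joining two nodes. The centerline
  runs from the `from` node through the `waypoints` (a list of `[x, y]`
  pairs, possibly empty) to the `to` node; every leg must be
  axis-aligned and consecutive legs perpendicular (90-degree turns).
  `width` and `height` are the cross-section sides. Segment length is
  derived from the centerline geometry.
- `boundary_conditions` — one entry per terminal: `type` `"pressure"`
  (value in Pa) or `"velocity"` (mean velocity in m/s, positive into the
  chip).

A netlist is solvable if it is connected and either at least one terminal
carries a pressure condition or the velocity inflows sum to zero.
Library-backed particle simulation additionally requires 200 um channel
widths and arm speeds inside the 0-2 cm/s envelope.
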
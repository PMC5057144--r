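# Wire-model PDB dialect

Skeletonized axonal tract models are exchanged in a dialect of the Protein
Data Bank (PDB) coordinate format, so that the models can be opened in any
molecular-graphics tool.  The dialect repurposes a handful of fields; all
other conventions follow PDB version 3.3 fixed-column layout.

## Records

- `REMARK   3` header lines describe the dialect and the anatomical axis
  convention.
- One `HETATM` record per node:

  | columns | field              | meaning in this dialect                     |
  |---------|--------------------|---------------------------------------------|
  | 1-6     | record name        | `HETATM`                                    |
  | 7-11    | atom serial        | global node number (1-based, <= 99999)      |
  | 13-16   | atom name          | node name, unique within its trace          |
  | 18-20   | residue name       | `TRC`                                       |
  | 22      | chain identifier   | trace-id page: `A` for traces 1-9999, `B` for 10000-19998, ... |
  | 23-26   | residue sequence   | trace id within the page (1-9999)           |
  | 31-38   | x (8.3)            | x coordinate in **micrometers** (not A)     |
  | 39-46   | y (8.3)            | y coordinate in micrometers                 |
  | 47-54   | z (8.3)            | z coordinate in micrometers                 |
  | 55-60   | occupancy          | always `1.00`                               |
  | 61-66   | temperature factor | node **diameter in micrometers**            |

- `CONECT` records list connections (unordered node pairs).  Each pair is
  written once, from the lower serial, at most four partners per record.
- `END` terminates the file.

## Conventions

- Trace id = `(chain index - 1) * 9999 + residue sequence`; traces are
  numbered serially from 1.
- Coordinates are Cartesian micrometers with the origin at the attenuation
  map origin; the -x/+x axis lies nearly along the dorsoventral direction,
  -y/+y left-to-right, -z/+z anteroposterior (right-handed).
- Coordinates must satisfy |value| < 10^5 um to fit the 8.3 field.
- Writing is canonical (fixed formatting, connections sorted ascending), so
  write -> read -> write is byte-identical.
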
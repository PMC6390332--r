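<?xml version="1.0"?>
<!DOCTYPE pathway SYSTEM "https://www.kegg.jp/kegg/xml/KGML_v0.7.2_.dtd">
<pathway name="path:demo0010" org="demo" number="0010" title="Demo signaling pathway">
  <entry id="1" name="hsa:10" type="gene"><graphics name="RTK"/></entry>
  <entry id="2" name="hsa:20 hsa:21" type="gene"><graphics name="RAS"/></entry>
  <entry id="3" name="hsa:30" type="gene"><graphics name="RAF"/></entry>
  <entry id="4" name="hsa:40" type="gene"><graphics name="MEK"/></entry>
  <entry id="5" name="hsa:50" type="gene"><graphics name="ERK"/></entry>
  <entry id="6" name="hsa:60" type="gene"><graphics name="PHOSPHATASE"/></entry>
  <entry id="7" name="cpd:C00165" type="compound"><graphics name="DAG"/></entry>
  <entry id="8" name="hsa:70" type="gene"><graphics name="PKC"/></entry>
  <relation entry1="1" entry2="2" type="PPrel"><subtype name="activation" value="--&gt;"/></relation>
  <relation entry1="2" entry2="3" type="PPrel"><subtype name="activation" value="--&gt;"/><subtype name="phosphorylation" value="+p"/></relation>
  <relation entry1="3" entry2="4" type="PPrel"><subtype name="activation" value="--&gt;"/><subtype name="phosphorylation" value="+p"/></relation>
  <relation entry1="4" entry2="5" type="PPrel"><subtype name="activation" value="--&gt;"/><subtype name="phosphorylation" value="+p"/></relation>
  <relation entry1="6" entry2="5" type="PPrel"><subtype name="inhibition" value="--|"/><subtype name="dephosphorylation" value="-p"/></relation>
  <relation entry1="1" entry2="7" type="PCrel"><subtype name="activation" value="--&gt;"/></relation>
  <relation entry1="7" entry2="8" type="PCrel"><subtype name="activation" value="--&gt;"/></relation>
  <relation entry1="8" entry2="5" type="PPrel"><subtype name="indirect effect" value="..&gt;"/></relation>
  <relation entry1="1" entry2="6" type="PPrel"><subtype name="binding/association" value="---"/></relation>
</pathway>
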
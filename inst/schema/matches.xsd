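<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="unqualified">
  <xs:element name="match_run">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="config">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="param" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="name" type="xs:string" use="required"/>
                  <xs:attribute name="value" type="xs:string" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="motif">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="point" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="id" type="xs:string" use="required"/>
                  <xs:attribute name="labels" type="xs:string" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
            <xs:attribute name="id" type="xs:string" use="required"/>
            <xs:attribute name="source" type="xs:string" use="required"/>
            <xs:attribute name="m" type="xs:positiveInteger" use="required"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="profile" minOccurs="0">
          <xs:complexType>
            <xs:attribute name="n_matched" type="xs:nonNegativeInteger" use="required"/>
            <xs:attribute name="n_missed" type="xs:nonNegativeInteger" use="required"/>
            <xs:attribute name="matched_weight" type="xs:decimal" use="required"/>
            <xs:attribute name="bandwidth" type="xs:decimal" use="required"/>
            <xs:attribute name="bandwidth_method" type="xs:string" use="required"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="matches">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="match" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="pair" maxOccurs="unbounded">
                      <xs:complexType>
                        <xs:attribute name="point" type="xs:string" use="required"/>
                        <xs:attribute name="residue" type="xs:string" use="required"/>
                        <xs:attribute name="label" type="xs:string" use="required"/>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                  <xs:attribute name="target" type="xs:string" use="required"/>
                  <xs:attribute name="ca_rmsd" type="xs:decimal" use="required"/>
                  <xs:attribute name="size" type="xs:positiveInteger" use="required"/>
                  <xs:attribute name="complete" type="xs:boolean" use="required"/>
                  <xs:attribute name="seed_key" type="xs:string" use="required"/>
                  <xs:attribute name="centroid_rmsd" type="xs:decimal"/>
                  <xs:attribute name="p_value" type="xs:decimal"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
            <xs:attribute name="n" type="xs:nonNegativeInteger" use="required"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="schema" type="xs:string" use="required"/>
      <xs:attribute name="table_schema" type="xs:string" use="required"/>
      <xs:attribute name="config_hash" type="xs:string" use="required"/>
    </xs:complexType>
  </xs:element>
</xs:schema>
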